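# DEG filtering and functional summarization.
#
# Gene records are rows of a data.frame with columns gene_id, length_nt,
# log2fc (15C vs 0C), padj, and optionally cog (single-letter category),
# pathways (semicolon-joined tags) and is_metabolic. Differential testing
# itself is upstream (DESeq2-style engines); this module starts at
# thresholding and summarization.

#' Transcripts per million from counts and gene lengths
#'
#' `rate_g = counts_g / length_kb; tpm_g = 1e6 * rate_g / sum(rates)`.
#' Columns of a count matrix are treated as samples.
#'
#' @param counts non-negative counts, vector or genes-x-samples matrix.
#' @param lengths_nt gene lengths in nucleotides (> 0).
#' @return TPM values with the shape of `counts`; each sample sums to 1e6
#'   (all-zero samples yield zeros with a warning).
#' @export
compute_tpm <- function(counts, lengths_nt) {
  if (any(lengths_nt <= 0)) stop("gene lengths must be positive")
  one <- function(cnt) {
    rate <- cnt / (lengths_nt / 1000)
    tot <- sum(rate)
    if (tot == 0) {
      warning("all-zero counts: TPM set to zero")
      return(rate)
    }
    1e6 * rate / tot
  }
  if (is.matrix(counts)) apply(counts, 2L, one) else one(counts)
}

#' Call differentially expressed genes by threshold
#'
#' Up: `padj < alpha` and `log2fc >= lfc_threshold`; down: `padj < alpha`
#' and `log2fc <= -lfc_threshold`. The p boundary is exclusive, the
#' fold-change boundary inclusive. Records with missing padj are skipped
#' (count messaged).
#'
#' @param records gene data.frame with `gene_id`, `log2fc`, `padj`.
#' @param lfc_threshold absolute log2 fold-change threshold (default 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return list with character vectors `up` and `down`.
#' @export
call_degs <- function(records, lfc_threshold = 1, alpha = 0.05) {
  if (!nrow(records)) return(list(up = character(0), down = character(0)))
  miss <- is.na(records$padj) | is.na(records$log2fc)
  if (any(miss)) {
    message(sum(miss), " record(s) without padj/log2fc skipped")
    records <- records[!miss, ]
  }
  ok <- records$padj < alpha
  list(up = records$gene_id[ok & records$log2fc >= lfc_threshold],
       down = records$gene_id[ok & records$log2fc <= -lfc_threshold])
}

#' COG category enrichment of a DEG set
#'
#' Per category, a 2x2 contingency table over the background of genes with
#' a COG annotation (in-category vs not, in-DEG-set vs not), tested with a
#' two-sided Fisher exact test (`alternative = "greater"` available) and
#' Benjamini-Hochberg adjusted across categories.
#'
#' @param deg_set character vector of gene ids (one direction).
#' @param records gene data.frame with `gene_id` and `cog`.
#' @param direction label stored in the output ("up" or "down").
#' @param alpha significance level on adjusted p.
#' @param alternative passed to [stats::fisher.test()] ("two.sided" default).
#' @return data.frame category, direction, a, b, c, d, odds_ratio, p_raw,
#'   p_adjusted, significant.
#' @export
cog_enrichment <- function(deg_set, records, direction = "up", alpha = 0.05,
                           alternative = "two.sided") {
  bg <- records[!is.na(records$cog) & nzchar(records$cog), ]
  if (!nrow(bg)) stop("no COG-annotated background genes")
  in_deg <- bg$gene_id %in% deg_set
  cats <- sort(unique(bg$cog))
  rows <- lapply(cats, function(cc) {
    in_cat <- bg$cog == cc
    a <- sum(in_cat & in_deg)
    b <- sum(in_cat & !in_deg)
    c_ <- sum(!in_cat & in_deg)
    d <- sum(!in_cat & !in_deg)
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                             alternative = alternative)
    data.frame(category = cc, direction = direction, a = a, b = b, c = c_, d = d,
               odds_ratio = unname(ft$estimate), p_raw = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_adjusted < alpha
  out
}

#' Pathway-level DEG fractions
#'
#' Percentage of each pathway's genes that are differentially expressed,
#' split by direction, plus the metabolic-gene share of all DEGs.
#'
#' @param up,down DEG id vectors from [call_degs()].
#' @param records gene data.frame with `gene_id`, `pathways`
#'   (semicolon-joined tags) and optionally `is_metabolic`.
#' @return data.frame pathway, n_genes, n_deg, pct_deg, pct_up, pct_down
#'   (empty pathways excluded); attribute `metabolic_deg_pct` gives
#'   100 * metabolic DEGs / DEGs rounded to 2 decimals.
#' @export
pathway_deg_fractions <- function(up, down, records) {
  deg <- union(up, down)
  pw_lists <- strsplit(ifelse(is.na(records$pathways), "", records$pathways), ";")
  pws <- sort(setdiff(unique(unlist(pw_lists)), ""))
  rows <- lapply(pws, function(pw) {
    genes <- records$gene_id[vapply(pw_lists, function(p) pw %in% p, logical(1))]
    n <- length(genes)
    if (!n) return(NULL)
    data.frame(pathway = pw, n_genes = n,
               n_deg = sum(genes %in% deg),
               pct_deg = 100 * sum(genes %in% deg) / n,
               pct_up = 100 * sum(genes %in% up) / n,
               pct_down = 100 * sum(genes %in% down) / n)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(pathway = character(0), n_genes = integer(0),
                                      n_deg = integer(0), pct_deg = numeric(0),
                                      pct_up = numeric(0), pct_down = numeric(0))
  if (!is.null(records$is_metabolic) && length(deg)) {
    n_met <- sum(records$is_metabolic[records$gene_id %in% deg], na.rm = TRUE)
    attr(out, "metabolic_deg_pct") <- round(100 * n_met / length(deg), 2)
    attr(out, "n_metabolic_deg") <- n_met
  }
  attr(out, "n_deg") <- length(deg)
  out
}
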