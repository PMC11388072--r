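#' Differential eccDNA abundance between two cohorts
#'
#' Per gene, a two-sided Wilcoxon rank-sum test compares the per-sample
#' normalized abundances of the tumor and control groups (exact null
#' distribution when the smaller group has at most 12 samples and there
#' are no ties, normal approximation with continuity correction
#' otherwise). The fold change is `log2((mean_tumor + c) / (mean_control
#' + c))` with pseudocount `c` defaulting to 1e-3 of the global mean
#' positive abundance. A gene is flagged significant when
#' `|log2FC| > 0.5` and `P < 0.01`; no multiple-testing correction is
#' applied by default (set `fdr = "BH"` to add an adjusted column — the
#' significance rule still uses the raw P).
#'
#' @param tumor,control lists of per-sample abundance tibbles
#'   ([gene_abundance()]), or genes-x-samples matrices with gene row
#'   names. At least 3 samples per group; shared gene universe.
#' @param pseudocount fold-change pseudocount (`NULL` = auto).
#' @param lfc_cut,p_cut significance thresholds.
#' @param fdr optional `p.adjust` method adding a `p_adj` column.
#' @return an `ecc_diff` object; use [tidy()] for the per-gene table and
#'   [glance()] for a one-row summary.
#' @export
differential_abundance <- function(tumor, control, pseudocount = NULL,
                                   lfc_cut = 0.5, p_cut = 0.01, fdr = NULL) {
  A_t <- abundance_matrix(tumor)
  A_c <- abundance_matrix(control)
  if (ncol(A_t) < 3 || ncol(A_c) < 3) abort("need >= 3 samples per group")
  genes <- rownames(A_t)
  if (!identical(genes, rownames(A_c))) {
    shared <- intersect(genes, rownames(A_c))
    if (length(shared) == 0) abort("no shared genes between groups")
    A_t <- A_t[shared, , drop = FALSE]
    A_c <- A_c[shared, , drop = FALSE]
    genes <- shared
  }
  if (is.null(pseudocount)) {
    pos <- c(A_t, A_c)
    pos <- pos[pos > 0]
    pseudocount <- if (length(pos)) 1e-3 * mean(pos) else 1e-3
  }
  exact <- min(ncol(A_t), ncol(A_c)) <= 12
  p <- vapply(seq_along(genes), function(i) {
    x <- A_t[i, ]; y <- A_c[i, ]
    if (all(x == 0) && all(y == 0)) return(1)
    suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  }, numeric(1))
  m_t <- rowMeans(A_t); m_c <- rowMeans(A_c)
  lfc <- ifelse(m_t == 0 & m_c == 0, 0,
                log2((m_t + pseudocount) / (m_c + pseudocount)))
  res <- tibble(gene_id = genes, mean_A_tumor = m_t, mean_A_control = m_c,
                log2fc = lfc, p_value = p,
                significant = abs(lfc) > lfc_cut & p < p_cut)
  if (!is.null(fdr)) res$p_adj <- p.adjust(res$p_value, method = fdr)
  structure(list(result = res, pseudocount = pseudocount,
                 n_tumor = ncol(A_t), n_control = ncol(A_c),
                 lfc_cut = lfc_cut, p_cut = p_cut),
            class = "ecc_diff")
}

# list of abundance tibbles (gene_id, A) or a matrix -> genes x samples matrix
abundance_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("abundance matrix needs gene row names")
    return(x)
  }
  stopifnot(is.list(x), length(x) > 0)
  genes <- x[[1]]$gene_id
  m <- vapply(x, function(tb) {
    if (!identical(tb$gene_id, genes)) {
      tb <- tb[match(genes, tb$gene_id), ]
    }
    tb$A
  }, numeric(length(genes)))
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes, paste0("s", seq_along(x))))
  m
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname differential_abundance
#' @param x an `ecc_diff` object.
#' @param ... unused.
#' @method tidy ecc_diff
#' @export
tidy.ecc_diff <- function(x, ...) x$result

#' @rdname differential_abundance
#' @method glance ecc_diff
#' @export
glance.ecc_diff <- function(x, ...) {
  tibble(n_genes = nrow(x$result),
         n_significant = sum(x$result$significant),
         n_up = sum(x$result$significant & x$result$log2fc > 0),
         n_down = sum(x$result$significant & x$result$log2fc < 0),
         n_tumor = x$n_tumor, n_control = x$n_control,
         pseudocount = x$pseudocount)
}

#' @export
print.ecc_diff <- function(x, ...) {
  cat("<ecc_diff> ", nrow(x$result), " genes, ",
      sum(x$result$significant), " significant (|log2FC| > ", x$lfc_cut,
      ", P < ", x$p_cut, ")\n", sep = "")
  print(head(x$result %>% arrange(.data$p_value), 10))
  invisible(x)
}

#' eccDNA-desert fraction of an abundance table
#'
#' Fraction of genes with no eccDNA start site (`J = 0`).
#'
#' @param table abundance tibble with a `J` column.
#' @return fraction in `[0, 1]`.
#' @export
desert_fraction <- function(table) {
  if (nrow(table) == 0) abort("empty abundance table")
  mean(table$J == 0)
}

#' Per-gene Spearman correlation between eccDNA abundance and expression
#'
#' Genes are retained only when their TPM exceeds `min_tpm` in every
#' sample; for the retained genes the Spearman correlation of abundance
#' vs expression across matched samples is reported with its P value.
#'
#' @param abundance genes x samples matrix (gene row names).
#' @param tpm expression matrix with identical dimensions and order.
#' @param min_tpm expression floor applied per sample.
#' @return tibble `gene_id`, `rho`, `p_value`, `n_samples`.
#' @export
mrna_ecc_correlation <- function(abundance, tpm, min_tpm = 5) {
  stopifnot(identical(dim(abundance), dim(tpm)))
  if (ncol(abundance) < 4) abort("need >= 4 matched samples for correlation")
  keep <- rownames(abundance)[apply(tpm > min_tpm, 1, all)]
  purrr::map_dfr(keep, function(g) {
    ct <- suppressWarnings(cor.test(abundance[g, ], tpm[g, ],
                                    method = "spearman"))
    tibble(gene_id = g, rho = unname(ct$estimate), p_value = ct$p.value,
           n_samples = ncol(abundance))
  })
}
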