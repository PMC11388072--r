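#' Plant clustered SNVs (kataegis) over a Poisson background
#'
#' Emits background SNVs as a per-chromosome Poisson process with the
#' stated mean inter-mutation distance, plus planted clusters of 6-15
#' SNVs with gaps drawn uniformly from 100-600 bp (so every planted
#' cluster satisfies the kataegis rule: >= 6 SNVs, mean gap <= 1000 bp).
#' A fraction of clusters is placed inside the supplied ecDNA intervals;
#' the remainder is uniform over the genome. Truth labels (`on_ecdna`,
#' `near_ecdna_10kb`, `none`) are computed from the final placement.
#'
#' @param ref output of [build_synthetic_genome()] (needs `genome`, `sizes`).
#' @param ecdna ecDNA interval tibble (may be empty).
#' @param config a [sim_config()]; only the seed is used.
#' @param n_clusters planted cluster count.
#' @param background_imd mean background inter-mutation distance (bp). A
#'   warning is issued below 5 kb (background clusters become likely).
#' @param frac_on_ecdna fraction of clusters placed inside ecDNA intervals.
#' @param dir optional directory; when given, writes `snvs.vcf` and
#'   `snv_truth.tsv`.
#' @return list with `snvs` (tibble: `chrom`, `pos` 0-based, `ref`, `alt`,
#'   `vaf`, `is_clustered`, `cluster_id`), `truth` (per-cluster tibble with
#'   `label`), and file `paths` when `dir` is given.
#' @export
plant_kataegis_snvs <- function(ref, ecdna, config, n_clusters = 5,
                                background_imd = 1e5, frac_on_ecdna = 0.6,
                                dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(ecdna) > 0) validate_intervals(ecdna, "ecdna")
  if (background_imd < 5000) {
    warn("background IMD < 5 kb: spurious background clusters are expected")
  }
  genome <- ref$genome
  sizes <- ref$sizes
  with_seed0(seed_for(config, "snvs"), {
    rows <- list()
    # background
    for (i in seq_len(nrow(sizes))) {
      pos <- cumsum(pmax(1L, as.integer(round(rexp(
        ceiling(2 * sizes$size[i] / background_imd) + 10, 1 / background_imd)))))
      pos <- pos[pos < sizes$size[i] - 1]
      if (length(pos) == 0) next
      rows[[length(rows) + 1]] <- tibble(chrom = sizes$chrom[i], pos = pos,
                                         cluster_id = NA_character_)
    }
    # planted clusters
    truth <- list()
    for (k in seq_len(n_clusters)) {
      n <- sample(6:15, 1)
      gaps <- sample(100:600, n - 1, replace = TRUE)
      span <- sum(gaps)
      on_ec <- nrow(ecdna) > 0 && runif(1) < frac_on_ecdna
      if (on_ec) {
        fit <- ecdna[(ecdna$end - ecdna$start) > span + 2, , drop = FALSE]
        if (nrow(fit) == 0) { on_ec <- FALSE } else {
          iv <- fit[sample.int(nrow(fit), 1), ]
          first <- iv$start + sample.int(iv$end - iv$start - span - 1, 1)
          ch <- iv$chrom
        }
      }
      if (!on_ec) {
        ci <- sample.int(nrow(sizes), 1, prob = sizes$size)
        ch <- sizes$chrom[ci]
        first <- sample.int(sizes$size[ci] - span - 2, 1)
      }
      pos <- first + c(0L, cumsum(gaps))
      cid <- sprintf("cluster_%02d", k)
      rows[[length(rows) + 1]] <- tibble(chrom = ch, pos = as.integer(pos),
                                         cluster_id = cid)
      truth[[k]] <- tibble(cluster_id = cid, chrom = ch,
                           first_pos = min(pos), last_pos = max(pos),
                           n_snvs = n,
                           mean_imd = (max(pos) - min(pos)) / (n - 1))
    }
    snvs <- bind_rows(rows) %>%
      distinct(.data$chrom, .data$pos, .keep_all = TRUE) %>%
      arrange(.data$chrom, .data$pos)
    # reference/alt bases and VAFs
    refb <- vapply(seq_len(nrow(snvs)), function(i) {
      as.character(Biostrings::subseq(genome[[snvs$chrom[i]]],
                                      snvs$pos[i] + 1L, snvs$pos[i] + 1L))
    }, character(1))
    bases <- c("A", "C", "G", "T")
    altb <- vapply(refb, function(b) sample(setdiff(bases, b), 1), character(1))
    snvs$ref <- refb
    snvs$alt <- altb
    snvs$is_clustered <- !is.na(snvs$cluster_id)
    snvs$vaf <- round(ifelse(snvs$is_clustered, stats::rbeta(nrow(snvs), 2, 6),
                             stats::rbeta(nrow(snvs), 5, 5)), 4)
    truth <- bind_rows(truth)
    truth$label <- cluster_truth_label(truth, ecdna)
    out <- list(snvs = snvs, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(vcf = file.path(dir, "snvs.vcf"),
                    truth_tsv = file.path(dir, "snv_truth.tsv"))
      write_snv_vcf(snvs, paths$vcf)
      readr::write_tsv(truth, paths$truth_tsv)
      out$paths <- paths
    }
    out
  })
}

# kyklonas-style truth label for a planted cluster
cluster_truth_label <- function(truth, ecdna) {
  vapply(seq_len(nrow(truth)), function(i) {
    if (nrow(ecdna) == 0) return("none")
    on_chr <- ecdna[ecdna$chrom == truth$chrom[i], , drop = FALSE]
    if (nrow(on_chr) == 0) return("none")
    inside <- any(truth$first_pos[i] < on_chr$end &
                    truth$last_pos[i] >= on_chr$start)
    if (inside) return("on_ecdna")
    bp <- c(on_chr$start, on_chr$end)
    d <- min(abs(outer(c(truth$first_pos[i], truth$last_pos[i]), bp, "-")))
    if (d <= 10000) "near_ecdna_10kb" else "none"
  }, character(1))
}

#' Simulate per-sample gene abundance tables with planted effects
#'
#' Generates matched tumor and control (adjacent-tissue) cohorts of
#' per-gene unique-junction counts: counts are Poisson with gene-specific
#' rates (gamma-distributed across genes) scaled by a per-sample size
#' factor, and a chosen set of genes receives an `effect`-fold rate
#' increase in the tumor group. Tables are normalized with
#' [gene_abundance_from_counts()] so each sums to 1e6.
#'
#' @param config a [sim_config()]; only the seed is used.
#' @param n_genes number of genes.
#' @param n_tumor,n_at samples per group.
#' @param n_diff number of genes planted with a tumor effect.
#' @param effect fold change of planted genes (1 = fully null).
#' @param base_rate mean per-gene expected junction count.
#' @return list with `tumor` and `at` (lists of abundance tibbles),
#'   `diff_genes` (planted gene ids) and `gene_lengths`.
#' @export
simulate_abundance_tables <- function(config, n_genes = 2000, n_tumor = 10,
                                      n_at = 10, n_diff = 50, effect = 4,
                                      base_rate = 20) {
  stopifnot(inherits(config, "sim_config"))
  with_seed0(seed_for(config, "tables"), {
    gene_id <- sprintf("gene_%05d", seq_len(n_genes))
    L <- as.integer(round(rlnorm(n_genes, log(8000), 0.6)))
    lambda <- stats::rgamma(n_genes, shape = 2, rate = 2 / base_rate)
    diff_genes <- sample(gene_id, n_diff)
    make <- function(n, boost) {
      lapply(seq_len(n), function(s) {
        sf <- exp(rnorm(1, 0, 0.2))
        lam <- lambda * sf
        lam[gene_id %in% diff_genes] <- lam[gene_id %in% diff_genes] * boost
        J <- rpois(n_genes, lam)
        gene_abundance_from_counts(tibble(gene_id = gene_id, J = J, L = L))
      })
    }
    list(tumor = make(n_tumor, effect), at = make(n_at, 1),
         diff_genes = diff_genes, gene_lengths = tibble(gene_id, L))
  })
}

#' Simulate an expression matrix coupled to eccDNA abundance
#'
#' Builds a TPM-like matrix whose per-gene values are a monotone function
#' of the abundance matrix plus log-normal noise, for exercising the
#' mRNA-eccDNA correlation analysis.
#'
#' @param abundance genes x samples numeric matrix.
#' @param noise_sd log-scale noise (0 gives a perfect monotone transform).
#' @param seed RNG seed.
#' @return matrix of the same shape.
#' @export
simulate_expression <- function(abundance, noise_sd = 0.5, seed = 1L) {
  with_seed0(seed, {
    base <- 10 + sqrt(abundance)
    base * exp(matrix(rnorm(length(abundance), 0, noise_sd),
                      nrow = nrow(abundance)))
  })
}
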