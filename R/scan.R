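## internal locus fit shared by the exported fit_locus, genome_scan and
## the permutation engine; `estimates = FALSE` skips the REML fit used
## only for reporting effect estimates/SEs/variance components
.fit_locus_core <- function(y, xa, xd, xi, fam, min_class_n = 1L,
                            null_ml = NULL, estimates = TRUE) {
  ok <- !is.na(y) & !is.na(xa) & !is.na(fam)
  y <- y[ok]; xa <- xa[ok]; xd <- xd[ok]; xi <- xi[ok]; fam <- fam[ok]
  counts <- c(AA = sum(xa == 1), AB = sum(xd == 1 & xi == 1),
              BA = sum(xd == 1 & xi == -1), BB = sum(xa == -1))
  out <- list(n_used = length(y), counts = counts,
              lods = c(mLOD = NA_real_, aLOD = NA_real_, dLOD = NA_real_,
                       iLOD = NA_real_),
              r = NA_real_, a = NA_real_, d = NA_real_, i = NA_real_,
              se_a = NA_real_, se_d = NA_real_, se_i = NA_real_,
              sigma2_family = NA_real_, sigma2_residual = NA_real_,
              status = "ok")
  if (any(counts < min_class_n)) {
    out$status <- "skipped_class_n"
    return(out)
  }
  if (length(unique(fam)) < 1L || length(y) < 6L) {
    out$status <- "skipped_too_few"
    return(out)
  }
  if (stats::var(y) < 1e-12 * max(1, mean(y)^2)) {
    out$lods[] <- 0
    out[c("r", "a", "d", "i")] <- list(mean(y), 0, 0, 0)
    out[c("se_a", "se_d", "se_i")] <- list(0, 0, 0)
    out[c("sigma2_family", "sigma2_residual")] <- list(0, 0)
    return(out)
  }
  ones <- rep(1, length(y))
  X_full <- cbind(`(Intercept)` = ones, x_a = xa, x_d = xd, x_i = xi)
  full <- fit_family_lmm(y, X_full, fam, REML = FALSE)
  if (is.null(null_ml) || !identical(null_ml$n, length(y))) {
    nf <- fit_family_lmm(y, cbind(`(Intercept)` = ones), fam, REML = FALSE)
    null_ml <- list(logLik = nf$logLik, n = length(y))
  }
  red_a <- fit_family_lmm(y, X_full[, -2, drop = FALSE], fam, REML = FALSE)
  red_d <- fit_family_lmm(y, X_full[, -3, drop = FALSE], fam, REML = FALSE)
  red_i <- fit_family_lmm(y, X_full[, -4, drop = FALSE], fam, REML = FALSE)
  lod <- function(red_ll) {
    max(0, (full$logLik - red_ll) / log(10))
  }
  out$lods <- c(mLOD = lod(null_ml$logLik), aLOD = lod(red_a$logLik),
                dLOD = lod(red_d$logLik), iLOD = lod(red_i$logLik))
  if (estimates) {
    reml <- fit_family_lmm(y, X_full, fam, REML = TRUE)
    out$r <- reml$beta[1]; out$a <- reml$beta[2]
    out$d <- reml$beta[3]; out$i <- reml$beta[4]
    out$se_a <- reml$se[2]; out$se_d <- reml$se[3]; out$se_i <- reml$se[4]
    out$sigma2_family <- reml$sigma2_f
    out$sigma2_residual <- reml$sigma2_e
  }
  out
}

#' Fit the a/d/i mixed model at one locus
#'
#' Fits `y = r + a*x_a + d*x_d + i*x_i + u_family + e` with a family
#' random intercept. Effect estimates, standard errors and variance
#' components come from the REML fit. LOD scores are log10 likelihood
#' ratios computed under maximum likelihood (REML likelihoods are not
#' comparable across fixed-effect structures): `mLOD` drops all three
#' index scores, `aLOD`/`dLOD`/`iLOD` drop one score each. Negative
#' LODs from numerical noise are clamped to zero. Individuals with
#' missing genotype at the locus are dropped.
#'
#' @param y numeric phenotype vector (adjusted for fixed covariates).
#' @param genotype ordered genotype codes at the marker (AA/AB/BA/BB),
#'   or a list with components `x_a`, `x_d`, `x_i` as from
#'   [encode_adi()].
#' @param family family identifiers (the sire:dam pair).
#' @param min_class_n minimum individuals required in each of the four
#'   ordered classes; below it the locus is skipped (default 1).
#' @return One-row data frame: n_used, class counts, r/a/d/i estimates,
#'   SEs, the four LODs, variance components and a status string.
#' @export
fit_locus <- function(y, genotype, family, min_class_n = 1L) {
  if (!is.list(genotype)) genotype <- encode_adi(genotype)
  core <- .fit_locus_core(y, genotype$x_a, genotype$x_d, genotype$x_i,
                          family, min_class_n = min_class_n)
  data.frame(n_used = core$n_used,
             n_AA = core$counts[["AA"]], n_AB = core$counts[["AB"]],
             n_BA = core$counts[["BA"]], n_BB = core$counts[["BB"]],
             r = core$r, a = core$a, d = core$d, i = core$i,
             se_a = core$se_a, se_d = core$se_d, se_i = core$se_i,
             mLOD = core$lods[["mLOD"]], aLOD = core$lods[["aLOD"]],
             dLOD = core$lods[["dLOD"]], iLOD = core$lods[["iLOD"]],
             sigma2_family = core$sigma2_family,
             sigma2_residual = core$sigma2_residual,
             status = core$status, stringsAsFactors = FALSE)
}

#' Genome scan with the orthogonal a/d/i mixed model
#'
#' Applies [fit_locus()] at every marker for every trait, preserving
#' map order. Phenotypes should already be adjusted for sex and
#' direction of cross ([adjust_phenotypes()]); the family random effect
#' absorbs shared-litter variation. Markers where any ordered genotype
#' class has fewer than `min_class_n` individuals are skipped for that
#' trait (status flag, never an abort).
#'
#' @param pheno adjusted `phenotype_table` (analyzable individuals).
#' @param geno `ordered_geno` matrix; rows must cover `pheno$id`.
#' @param map the `genetic_map` (defines scan order).
#' @param traits traits to scan (default: all trait columns).
#' @param min_class_n per-class minimum (default 5).
#' @return Data frame of class `adi_scan`: one row per (trait, marker),
#'   with effect estimates, SEs, the four LODs, variance components and
#'   status; metadata (covariates, model choices) in attributes.
#' @export
genome_scan <- function(pheno, geno, map, traits = NULL, min_class_n = 5L) {
  if (is.null(traits)) traits <- trait_names(pheno)
  geno <- geno[pheno$id, map$marker_id, drop = FALSE]
  idx <- encode_adi(geno)
  fam <- pheno$family_id
  rows <- vector("list", length(traits) * nrow(map))
  k <- 0L
  for (tr in traits) {
    y <- pheno[[tr]]
    null_ml <- NULL
    ok_all <- !is.na(y) & !is.na(fam)
    if (sum(ok_all) >= 6L && stats::var(y[ok_all]) > 1e-12) {
      nf <- fit_family_lmm(y[ok_all],
                           cbind(`(Intercept)` = rep(1, sum(ok_all))),
                           fam[ok_all], REML = FALSE)
      null_ml <- list(logLik = nf$logLik, n = sum(ok_all))
    }
    for (m in seq_len(nrow(map))) {
      core <- .fit_locus_core(y, idx$x_a[, m], idx$x_d[, m], idx$x_i[, m],
                              fam, min_class_n = min_class_n,
                              null_ml = null_ml)
      k <- k + 1L
      rows[[k]] <- data.frame(
        trait = tr, marker_id = map$marker_id[m],
        chromosome = map$chromosome[m], position_cM = map$position_cM[m],
        n_used = core$n_used, a = core$a, d = core$d, i = core$i,
        se_a = core$se_a, se_d = core$se_d, se_i = core$se_i,
        mLOD = core$lods[["mLOD"]], aLOD = core$lods[["aLOD"]],
        dLOD = core$lods[["dLOD"]], iLOD = core$lods[["iLOD"]],
        sigma2_family = core$sigma2_family,
        sigma2_residual = core$sigma2_residual,
        status = core$status, stringsAsFactors = FALSE)
    }
  }
  scan <- do.call(rbind, rows)
  rownames(scan) <- NULL
  attr(scan, "metadata") <- list(
    traits = traits, min_class_n = min_class_n,
    lod_likelihood = "ML", variance_components = "REML",
    covariates = "pre-adjusted (sex, grandmaternal_line)")
  class(scan) <- c("adi_scan", "data.frame")
  scan
}

#' Read / write scan results as tab-separated text
#'
#' @param path file path.
#' @return `read_scan_tsv` returns an `adi_scan` data frame.
#' @export
read_scan_tsv <- function(path) {
  scan <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(scan) <- c("adi_scan", "data.frame")
  scan
}

#' @rdname read_scan_tsv
#' @param scan an `adi_scan`.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
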