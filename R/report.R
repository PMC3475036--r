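#' Published QTL effect table fixture
#'
#' Loads the packaged effect table of identified loci: one row per
#' (locus, trait) with positions, support interval, the four LOD
#' scores, and boolean significance flags encoding which statistics
#' were reported significant (boldface in print — thresholds per trait
#' were permutation-derived and are not recomputable from the table, so
#' they ship as explicit flags).
#'
#' @param path optional path to an alternative table in the same
#'   dialect.
#' @return Data frame of class `qtl_table_fixture`.
#' @export
load_qtl_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_effects.tsv", package = "poeqtl")
  }
  fix <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cl in c("mLOD_sig", "aLOD_sig", "dLOD_sig", "iLOD_sig")) {
    fix[[cl]] <- as.logical(fix[[cl]])
  }
  class(fix) <- c("qtl_table_fixture", "data.frame")
  fix
}

#' Published per-trait variance-decomposition table fixture
#'
#' Loads the packaged table of percent phenotypic variance explained
#' per trait: counts of loci and of significant a/d/i effects, and the
#' per-effect R-squared columns (percent).
#'
#' @param path optional path to an alternative table in the same
#'   dialect.
#' @return Data frame of class `r2_table_fixture`.
#' @export
load_r2_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_r2.tsv", package = "poeqtl")
  }
  fix <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(fix) <- c("r2_table_fixture", "data.frame")
  fix
}

#' Count significant single-effect entries in an effect table
#'
#' Counts (locus, trait) entries flagged significant for each
#' single-effect statistic (additive, dominance, imprinting).
#'
#' @param fixture a `qtl_table_fixture`.
#' @return Named integer vector `c(a = , d = , i = )`.
#' @export
summarize_effect_counts <- function(fixture) {
  c(a = sum(fixture$aLOD_sig), d = sum(fixture$dLOD_sig),
    i = sum(fixture$iLOD_sig))
}

#' Summarise loci in an effect table
#'
#' Returns the number of distinct loci, the number affecting exactly
#' one trait, and the number whose primary (first-listed) trait has the
#' imprinting LOD as the largest of the three single-effect LODs.
#'
#' @param fixture a `qtl_table_fixture`.
#' @return List with `n_qtl`, `n_single_trait_qtl`,
#'   `n_imprinting_top_qtl`.
#' @export
summarize_qtl <- function(fixture) {
  qtl <- unique(fixture$qtl)
  n_traits <- vapply(qtl, function(q) {
    length(unique(fixture$trait[fixture$qtl == q]))
  }, integer(1))
  imprint_top <- vapply(qtl, function(q) {
    first <- fixture[fixture$qtl == q, ][1L, ]
    first$iLOD > first$aLOD && first$iLOD > first$dLOD
  }, logical(1))
  list(n_qtl = length(qtl),
       n_single_trait_qtl = sum(n_traits == 1L),
       n_imprinting_top_qtl = sum(imprint_top))
}

#' Per-trait totals of percent variance explained
#'
#' Sums each trait's per-effect R-squared components by orthogonal
#' summation ([total_r2()]).
#'
#' @param fixture an `r2_table_fixture`.
#' @return Named numeric vector of per-trait totals (percent).
#' @export
trait_totals <- function(fixture) {
  tot <- vapply(seq_len(nrow(fixture)), function(r) {
    total_r2(c(fixture$R2_a[r], fixture$R2_d[r], fixture$R2_i[r]))
  }, numeric(1))
  stats::setNames(tot, fixture$trait)
}

#' Ordered-class means at a marker
#'
#' Per-class mean, standard error and count of a phenotype over the
#' four ordered genotype classes — the data behind a reciprocal-
#' heterozygote bar plot. Raw (uncorrected) or adjusted phenotypes can
#' be passed; an empty class is reported with n = 0 and NA mean.
#'
#' @param y phenotype vector.
#' @param genotype ordered codes at the marker, aligned with `y`.
#' @return Data frame with columns class, mean, se, n.
#' @export
genotype_means <- function(y, genotype) {
  out <- lapply(c("AA", "AB", "BA", "BB"), function(cl) {
    v <- y[!is.na(genotype) & genotype == cl & !is.na(y)]
    data.frame(class = cl,
               mean = if (length(v)) mean(v) else NA_real_,
               se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                    else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Decompose phenotypic variance over called QTL
#'
#' For every (locus, trait) attachment in a set of QTL calls, converts
#' the significant effect estimates into percent phenotypic variance
#' (a^2/2, d^2/4, i^2/2 over the trait's variance) and sums per trait
#' by orthogonality. An effect enters the total only when its own LOD
#' reached the pointwise cutoff at the locus peak.
#'
#' @param calls a `qtl_calls` object from [call_qtl()].
#' @param pheno the adjusted `phenotype_table` the scan used (defines
#'   Vp per trait).
#' @return Data frame: trait, n_loci, R2_a, R2_d, R2_i, total_R2
#'   (percent).
#' @export
variance_decomposition <- function(calls, pheno) {
  eff <- calls$effects
  traits <- unique(eff$trait)
  rows <- lapply(traits, function(tr) {
    sub <- eff[eff$trait == tr, , drop = FALSE]
    Vp <- stats::var(pheno[[tr]], na.rm = TRUE)
    r2a <- sum(vapply(seq_len(nrow(sub)), function(k) {
      if (sub$aLOD_pw[k]) r2_effect(sub$a[k], "a", Vp) else 0
    }, numeric(1)))
    r2d <- sum(vapply(seq_len(nrow(sub)), function(k) {
      if (sub$dLOD_pw[k]) r2_effect(sub$d[k], "d", Vp) else 0
    }, numeric(1)))
    r2i <- sum(vapply(seq_len(nrow(sub)), function(k) {
      if (sub$iLOD_pw[k]) r2_effect(sub$i[k], "i", Vp) else 0
    }, numeric(1)))
    data.frame(trait = tr, n_loci = nrow(sub), R2_a = r2a, R2_d = r2d,
               R2_i = r2i, total_R2 = total_r2(c(r2a, r2d, r2i)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
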