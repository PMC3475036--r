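#' Classify the parent-of-origin effect pattern at a locus
#'
#' At a locus with a significant imprinting effect, the configuration
#' of the a/d/i genotypic values identifies the expression pattern.
#' Pure paternal expression (phenotype tracks the paternally inherited
#' allele) forces i = a and d = 0; pure maternal expression forces
#' i = -a and d = 0. The bipolar pattern — the two reciprocal
#' heterozygotes differ from each other but the homozygotes do not —
#' corresponds to a significant i with no additive effect. Everything
#' else is binned as "other".
#'
#' @param effects a `genotypic_effects` list (fields a, d, i).
#' @param a_significant,d_significant,i_significant logical presence
#'   flags for each effect (e.g. LOD at or above the pointwise 1.3
#'   cutoff); `i_significant` must be TRUE — classification is only
#'   attempted at parent-of-origin loci.
#' @param ratio_tol tolerance on |i/a| for parental-expression calls:
#'   the ratio must lie in `[1/ratio_tol, ratio_tol]` (default 2).
#' @return List of class `pattern_call`: `pattern` (one of
#'   "paternal_expression", "maternal_expression", "bipolar", "other")
#'   and `evidence` (the flags and the i/a ratio, NA when a is absent).
#' @export
classify_pattern <- function(effects, a_significant, d_significant,
                             i_significant, ratio_tol = 2) {
  if (!isTRUE(i_significant)) {
    stop("classification requires a significant imprinting effect")
  }
  if (ratio_tol < 1) stop("ratio_tol must be >= 1")
  a <- effects$a
  i <- effects$i
  ratio <- if (a_significant && a != 0) i / a else NA_real_
  pattern <- "other"
  if (!a_significant) {
    pattern <- "bipolar"
  } else if (!d_significant && !is.na(ratio) &&
             abs(ratio) >= 1 / ratio_tol && abs(ratio) <= ratio_tol) {
    pattern <- if (ratio > 0) "paternal_expression" else "maternal_expression"
  }
  out <- list(pattern = pattern,
              evidence = list(a_significant = a_significant,
                              d_significant = d_significant,
                              i_significant = i_significant,
                              i_over_a_ratio = ratio))
  class(out) <- "pattern_call"
  out
}

#' Discriminate genomic imprinting from a maternal genetic effect
#'
#' A maternal genetic effect — the dam's genotype acting on offspring
#' through the environment she provides — can mimic an imprinting
#' pattern: heterozygous offspring of homozygous dams differ by dam
#' genotype, not by parent-of-origin of their own alleles. Under true
#' imprinting the reciprocal-heterozygote contrast is the same whatever
#' the mother's genotype. The test augments the locus mixed model with
#' a mother-class term (homozygous vs heterozygous dam) and the
#' x_i-by-mother-class interaction, and likelihood-ratio-tests the
#' interaction (ML, 1 df): a significant interaction indicates a
#' maternal genetic effect, otherwise the parent-of-origin signal is
#' attributed to imprinting.
#'
#' @param y adjusted phenotype vector.
#' @param genotype offspring ordered genotype codes at the locus.
#' @param dam_genotype dam unordered codes ("A"/"H"/"B") at the locus,
#'   aligned with `y`.
#' @param family family identifiers.
#' @param alpha test level (default 0.05).
#' @param min_n minimum informative (heterozygous) offspring required
#'   in each mother class; below it the verdict is "inconclusive"
#'   (default 5).
#' @return List of class `maternal_test`: `interaction_estimate`,
#'   `p_value`, `verdict` ("imprinting", "maternal_effect" or
#'   "inconclusive") and `n_by_mother_class` (informative offspring
#'   counts).
#' @export
maternal_vs_imprinting <- function(y, genotype, dam_genotype, family,
                                   alpha = 0.05, min_n = 5L) {
  idx <- encode_adi(genotype)
  ok <- !is.na(y) & !is.na(idx$x_a) & !is.na(dam_genotype) & !is.na(family)
  y <- y[ok]
  xa <- idx$x_a[ok]; xd <- idx$x_d[ok]; xi <- idx$x_i[ok]
  dam <- dam_genotype[ok]
  fam <- family[ok]
  het <- xd == 1
  if (!any(het)) stop("no heterozygous offspring: the parent-of-origin ",
                      "contrast is undefined")
  mother_het <- as.numeric(dam == "H")
  n_by <- c(hom_mother = sum(het & mother_het == 0),
            het_mother = sum(het & mother_het == 1))
  base <- list(interaction_estimate = NA_real_, p_value = NA_real_,
               verdict = "inconclusive", n_by_mother_class = n_by)
  class(base) <- "maternal_test"
  if (any(n_by < min_n)) return(base)

  X_full <- cbind(`(Intercept)` = rep(1, length(y)), x_a = xa, x_d = xd,
                  x_i = xi, mother_het = mother_het,
                  xi_by_mother = xi * mother_het)
  X_red <- X_full[, -6L, drop = FALSE]
  full <- fit_family_lmm(y, X_full, fam, REML = FALSE)
  red <- fit_family_lmm(y, X_red, fam, REML = FALSE)
  lrt <- max(0, 2 * (full$logLik - red$logLik))
  p <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
  base$interaction_estimate <- full$beta[6L]
  base$p_value <- p
  base$verdict <- if (p < alpha) "maternal_effect" else "imprinting"
  base
}
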