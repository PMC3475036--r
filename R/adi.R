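#' Orthogonal additive/dominance/imprinting index scores
#'
#' Assigns each ordered genotype the genotypic index scores of the
#' orthogonal a/d/i model: AA -> (1, 0, 0), AB -> (0, 1, 1),
#' BA -> (0, 1, -1), BB -> (-1, 0, 0). The additive score contrasts the
#' homozygotes, the dominance score marks heterozygosity, and the
#' imprinting (parent-of-origin) score contrasts the reciprocal
#' heterozygotes AB and BA. Missing genotypes yield missing scores.
#'
#' @param geno character vector or matrix of ordered codes AA/AB/BA/BB.
#' @return List with elements `x_a`, `x_d`, `x_i`, each the same shape
#'   as `geno`.
#' @export
encode_adi <- function(geno) {
  xa <- c(AA = 1, AB = 0, BA = 0, BB = -1)
  xd <- c(AA = 0, AB = 1, BA = 1, BB = 0)
  xi <- c(AA = 0, AB = 1, BA = -1, BB = 0)
  shape <- function(v) {
    if (is.matrix(geno)) {
      matrix(v, nrow(geno), ncol(geno), dimnames = dimnames(geno))
    } else {
      stats::setNames(v, names(geno))
    }
  }
  g <- as.character(geno)
  bad <- !is.na(g) & !(g %in% names(xa))
  if (any(bad)) stop("invalid ordered genotype codes: ",
                     paste(unique(g[bad]), collapse = ", "))
  list(x_a = shape(unname(xa[g])), x_d = shape(unname(xd[g])),
       x_i = shape(unname(xi[g])))
}

#' Genotypic values from ordered class means
#'
#' Inverts the orthogonal a/d/i design on the four ordered-class means:
#' `r = (mAA + mBB)/2` (reference point, the homozygote midpoint),
#' `a = (mAA - mBB)/2` (half the homozygote difference),
#' `d = (mAB + mBA)/2 - r` (heterozygote mean minus homozygote
#' midpoint), and `i = (mAB - mBA)/2` (half the difference between
#' reciprocal heterozygotes).
#'
#' @param mAA,mAB,mBA,mBB ordered-class means (trait units).
#' @return List of class `genotypic_effects` with `r`, `a`, `d`, `i`.
#' @export
genotypic_values_from_means <- function(mAA, mAB, mBA, mBB) {
  eff <- list(r = (mAA + mBB) / 2,
              a = (mAA - mBB) / 2,
              d = (mAB + mBA) / 2 - (mAA + mBB) / 2,
              i = (mAB - mBA) / 2)
  class(eff) <- "genotypic_effects"
  eff
}

#' Reconstruct ordered class means from genotypic values
#'
#' The forward map of the orthogonal model: AA = r + a, AB = r + d + i,
#' BA = r + d - i, BB = r - a. Inverse of
#' [genotypic_values_from_means()].
#'
#' @param effects a `genotypic_effects` list (or any list with r, a, d, i).
#' @return Named numeric vector of the four ordered class means.
#' @export
class_means_from_values <- function(effects) {
  with(effects, c(AA = r + a, AB = r + d + i, BA = r + d - i, BB = r - a))
}

#' Adjust phenotypes for fixed covariates
#'
#' Residualises each trait on sex and direction-of-cross (grandmaternal
#' line) indicators by ordinary least squares, then re-centres the
#' residuals at the trait's grand mean so values stay in trait units.
#' Covariates with a single observed level are skipped with a warning.
#' Only analyzable individuals are adjusted and returned.
#'
#' @param pheno a `phenotype_table`.
#' @param covariates columns to adjust for (default sex and
#'   grandmaternal_line).
#' @return A `phenotype_table` of analyzable individuals with adjusted
#'   trait values.
#' @export
adjust_phenotypes <- function(pheno,
                              covariates = c("sex", "grandmaternal_line")) {
  out <- pheno[pheno$analyzable, , drop = FALSE]
  keep <- character(0)
  for (cv in covariates) {
    if (length(unique(out[[cv]])) > 1L) {
      keep <- c(keep, cv)
    } else {
      warning("covariate '", cv, "' has a single level; skipped")
    }
  }
  if (length(keep) > 0L) {
    X <- stats::model.matrix(
      stats::reformulate(keep), data = out)
    for (tr in trait_names(out)) {
      y <- out[[tr]]
      fit <- stats::lm.fit(X, y)
      out[[tr]] <- as.numeric(fit$residuals + mean(y))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Percent phenotypic variance explained by one genotypic effect
#'
#' Under the orthogonal model with balanced ordered-genotype classes the
#' genotypic variance contributed by each effect is a^2/2, d^2/4 and
#' i^2/2; dividing by the phenotypic variance Vp and scaling by 100
#' gives the percent variance explained.
#'
#' @param value effect estimate (trait units).
#' @param effect_type one of "a", "d", "i".
#' @param Vp phenotypic variance (> 0, squared trait units).
#' @return Percent of phenotypic variance.
#' @export
r2_effect <- function(value, effect_type = c("a", "d", "i"), Vp) {
  effect_type <- match.arg(effect_type)
  if (!is.numeric(Vp) || Vp <= 0) stop("Vp must be positive")
  frac <- switch(effect_type,
                 a = value^2 / 2,
                 d = value^2 / 4,
                 i = value^2 / 2)
  100 * frac / Vp
}

#' Sum percent-variance components
#'
#' Because the a/d/i model is orthogonal, per-effect percents of
#' phenotypic variance add; the total for a trait is the arithmetic sum
#' of its included components.
#'
#' @param components numeric vector of non-negative percents (possibly
#'   empty).
#' @return Their sum (0 for an empty vector).
#' @export
total_r2 <- function(components) {
  if (length(components) == 0L) return(0)
  if (any(components < 0)) stop("components must be non-negative")
  sum(components)
}
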