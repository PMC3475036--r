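#' Specify a trait's generative architecture
#'
#' A trait is generated as
#' `y = grand_mean + sex_effect * male + cross_direction_effect * (grandmaternal_line == "B")
#'    + sum_q (a_q x_a + d_q x_d + i_q x_i) + u_family + m * damB + e`
#' where the index scores x are the orthogonal additive/dominance/
#' imprinting encoding of the individual's ordered genotype at each QTL
#' marker, `u_family ~ N(0, family_sd^2)` is shared by full sibs,
#' `damB` is the number of B alleles in the dam's unordered genotype at
#' the maternal-effect locus, and `e ~ N(0, residual_sd^2)`.
#'
#' @param trait_name trait label (trait units are the trait's own).
#' @param grand_mean reference point of the generative model.
#' @param qtls list of lists with fields `chromosome`, `position_cM`,
#'   `a`, `d`, `i` (trait units).
#' @param family_sd,residual_sd non-negative standard deviations.
#' @param sex_effect added to males.
#' @param cross_direction_effect added to descendants of the B-line
#'   matriline.
#' @param maternal_effect `NULL`, or a list with `chromosome`,
#'   `position_cM` and `m_per_maternal_B_allele` — an additive effect of
#'   the dam's B-allele count, the confoundable-with-imprinting form
#'   used to exercise the discrimination test.
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(trait_name, grand_mean = 0, qtls = list(),
                       family_sd = 0, residual_sd = 1, sex_effect = 0,
                       cross_direction_effect = 0, maternal_effect = NULL) {
  if (family_sd < 0 || residual_sd < 0) {
    stop("family_sd and residual_sd must be non-negative")
  }
  spec <- list(trait_name = trait_name, grand_mean = grand_mean,
               qtls = qtls, family_sd = family_sd,
               residual_sd = residual_sd, sex_effect = sex_effect,
               cross_direction_effect = cross_direction_effect,
               maternal_effect = maternal_effect)
  class(spec) <- "trait_spec"
  spec
}

#' Default trait architectures
#'
#' Eight traits emulating the architecture of muscle and obesity traits
#' in a hyper-muscular mouse intercross: a pleiotropic additive locus on
#' chromosome 1 shared by the mass traits, an imprinted body-weight
#' locus on chromosome 12, a bipolar imprinted locus on chromosome 19
#' affecting the glycolytic traits, a dominance locus on chromosome 15,
#' plus sex and cross-direction covariates and family variance.
#' Magnitudes are illustrative, in each trait's own units.
#'
#' @return Named list of `trait_spec` objects.
#' @export
default_trait_specs <- function() {
  specs <- list(
    trait_spec("Body weight", grand_mean = 35,
               qtls = list(list(chromosome = 1, position_cM = 13.3,
                                a = 1.0, d = 0, i = 0),
                           list(chromosome = 12, position_cM = 9.7,
                                a = 0, d = 0, i = 0.7),
                           list(chromosome = 17, position_cM = 40,
                                a = 0.8, d = 0, i = 0)),
               family_sd = 1.0, residual_sd = 2.2,
               sex_effect = 6, cross_direction_effect = 0.5),
    trait_spec("Muscle mass", grand_mean = 1.5,
               qtls = list(list(chromosome = 2, position_cM = 49,
                                a = 0.06, d = 0.02, i = 0),
                           list(chromosome = 15, position_cM = 58,
                                a = 0, d = 0.06, i = 0)),
               family_sd = 0.05, residual_sd = 0.12,
               sex_effect = 0.25, cross_direction_effect = 0.02),
    trait_spec("Fat mass", grand_mean = 8,
               qtls = list(list(chromosome = 1, position_cM = 13.3,
                                a = 1.1, d = 0, i = 0)),
               family_sd = 0.6, residual_sd = 1.4,
               sex_effect = 1.5, cross_direction_effect = 0.3),
    trait_spec("Lean mass", grand_mean = 24,
               qtls = list(list(chromosome = 1, position_cM = 13.3,
                                a = 0.7, d = 0, i = 0),
                           list(chromosome = 2, position_cM = 49,
                                a = 0.6, d = 0, i = 0)),
               family_sd = 0.8, residual_sd = 1.6,
               sex_effect = 4, cross_direction_effect = 0.4),
    trait_spec("Glycolytic potential", grand_mean = 110,
               qtls = list(list(chromosome = 19, position_cM = 23.5,
                                a = 0, d = 0, i = 6)),
               family_sd = 5, residual_sd = 13,
               sex_effect = 5, cross_direction_effect = 2),
    trait_spec("M. quadriceps", grand_mean = 0.42,
               qtls = list(list(chromosome = 2, position_cM = 49,
                                a = 0.015, d = 0, i = 0)),
               family_sd = 0.015, residual_sd = 0.035,
               sex_effect = 0.07, cross_direction_effect = 0.005),
    trait_spec("M. longissimus", grand_mean = 0.33,
               qtls = list(list(chromosome = 6, position_cM = 5.3,
                                a = 0.012, d = 0, i = 0.006),
                           list(chromosome = 8, position_cM = 36,
                                a = 0.012, d = 0, i = 0)),
               family_sd = 0.012, residual_sd = 0.03,
               sex_effect = 0.05, cross_direction_effect = 0.004),
    trait_spec("Glycogen content", grand_mean = 13,
               qtls = list(list(chromosome = 19, position_cM = 23.5,
                                a = 0, d = 0, i = 0.7)),
               family_sd = 0.6, residual_sd = 1.6,
               sex_effect = 0.6, cross_direction_effect = 0.2))
  names(specs) <- vapply(specs, function(s) s$trait_name, character(1))
  specs
}

#' Simulate phenotypes from a pedigree and ordered genotypes
#'
#' Generates one value per phenotyped individual (F2 and F3) and trait
#' under the generative model documented in [trait_spec()]. QTL
#' positions are resolved to the nearest marker on their chromosome
#' (error if the chromosome is absent from the map).
#'
#' @param ped a `pedigree`.
#' @param geno an `ordered_geno` matrix covering all of `ped`.
#' @param map the `genetic_map` used to simulate `geno`.
#' @param specs list of `trait_spec` objects.
#' @param seed integer seed.
#' @return Data frame of class `phenotype_table`: `id`, `sex`,
#'   `grandmaternal_line`, `family_id`, `analyzable`, then one column
#'   per trait.
#' @export
simulate_phenotypes <- function(ped, geno, map, specs = default_trait_specs(),
                                seed = 1L) {
  set.seed(seed)
  keep <- ped$generation %in% c("F2", "F3")
  sub <- ped[keep, , drop = FALSE]
  out <- data.frame(id = sub$id, sex = sub$sex,
                    grandmaternal_line = sub$grandmaternal_line,
                    family_id = sub$family_id, analyzable = sub$analyzable,
                    stringsAsFactors = FALSE)
  fam_levels <- unique(sub$family_id)
  dam_of <- sub$dam

  for (spec in specs) {
    y <- rep(spec$grand_mean, nrow(sub))
    y <- y + spec$sex_effect * (sub$sex == "male")
    y <- y + spec$cross_direction_effect * (sub$grandmaternal_line == "B")
    for (q in spec$qtls) {
      mk <- nearest_marker(map, q$chromosome, q$position_cM)
      idx <- encode_adi(geno[sub$id, mk])
      y <- y + q$a * idx$x_a + q$d * idx$x_d + q$i * idx$x_i
    }
    if (!is.null(spec$maternal_effect)) {
      me <- spec$maternal_effect
      mk <- nearest_marker(map, me$chromosome, me$position_cM)
      dam_geno <- unorder(geno[dam_of, mk, drop = FALSE])[, 1]
      damB <- c(A = 0, H = 1, B = 2)[dam_geno]
      y <- y + me$m_per_maternal_B_allele * damB
    }
    u <- stats::rnorm(length(fam_levels), 0, spec$family_sd)
    names(u) <- fam_levels
    y <- y + u[sub$family_id]
    y <- y + stats::rnorm(nrow(sub), 0, spec$residual_sd)
    out[[spec$trait_name]] <- as.numeric(y)
  }
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Read / write phenotype tables as CSV
#'
#' Columns: id, sex, grandmaternal_line, family_id, analyzable, then one
#' column per trait.
#'
#' @param path file path.
#' @return `read_phenotypes_csv` returns a `phenotype_table`.
#' @export
read_phenotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$analyzable <- as.logical(df$analyzable)
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' @rdname read_phenotypes_csv
#' @param pheno a `phenotype_table`.
#' @export
write_phenotypes_csv <- function(pheno, path) {
  utils::write.csv(as.data.frame(pheno), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Trait columns of a phenotype table
#'
#' @param pheno a `phenotype_table`.
#' @return Character vector of trait column names.
#' @export
trait_names <- function(pheno) {
  setdiff(names(pheno), c("id", "sex", "grandmaternal_line", "family_id",
                          "analyzable"))
}

#' Read a simulation configuration from YAML
#'
#' The YAML file may contain `sizes` (fields of [cross_config()]),
#' `seed`, and `traits` (a list of [trait_spec()] field sets).
#'
#' @param path YAML file path.
#' @return List with elements `config` (`cross_config`), `seed` and
#'   `specs` (list of `trait_spec`).
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(cross_config, as.list(raw$sizes %||% list()))
  specs <- lapply(raw$traits %||% list(), function(tr) {
    do.call(trait_spec, tr)
  })
  if (length(specs)) {
    names(specs) <- vapply(specs, function(s) s$trait_name, character(1))
  }
  list(config = cfg, seed = raw$seed %||% 1L, specs = specs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
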