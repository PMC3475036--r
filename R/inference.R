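#' Genome-wide significance thresholds by permutation
#'
#' Destroys the genotype-phenotype association under the null while
#' keeping the trait's family structure: each permutation shuffles the
#' (phenotype, family) rows as a unit against the genotype rows, the
#' full scan is re-run, and the genome-wide maximum of each statistic
#' (mLOD, aLOD, dLOD, iLOD) per trait is recorded. The threshold is the
#' empirical `(1 - alpha)` quantile, taken as the
#' `ceiling((1 - alpha) * n_perm)`-th order statistic of the maxima.
#'
#' @param pheno adjusted `phenotype_table`.
#' @param geno `ordered_geno` matrix covering `pheno$id`.
#' @param map the `genetic_map`.
#' @param traits traits to permute (default all).
#' @param n_perm number of permutations (default 1000; must allow a
#'   meaningful quantile, i.e. `n_perm >= 1/alpha`).
#' @param alpha genome-wide type-I rate (default 0.05).
#' @param pointwise_lod pointwise LOD cutoff carried into calling
#'   (default 1.3, the conventional p <= 0.05 pointwise level).
#' @param seed integer seed for the permutation stream.
#' @param min_class_n per-class minimum passed to the scan.
#' @return List of class `threshold_set`: `genomewide` (per trait, a
#'   named vector over the four statistics), `maxima` (per trait, an
#'   `n_perm` x 4 matrix of null maxima), plus alpha, n_perm,
#'   pointwise_lod and seed.
#' @export
permutation_thresholds <- function(pheno, geno, map, traits = NULL,
                                   n_perm = 1000L, alpha = 0.05,
                                   pointwise_lod = 1.3, seed = 1L,
                                   min_class_n = 5L) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  if (n_perm < 1 / alpha) {
    stop("n_perm too small for alpha = ", alpha,
         ": the (1 - alpha) quantile of ", n_perm,
         " maxima is not meaningful")
  }
  if (is.null(traits)) traits <- trait_names(pheno)
  geno <- geno[pheno$id, map$marker_id, drop = FALSE]
  idx <- encode_adi(geno)
  fam <- pheno$family_id
  n <- nrow(pheno)
  stats_names <- c("mLOD", "aLOD", "dLOD", "iLOD")
  maxima <- lapply(traits, function(tr) {
    matrix(NA_real_, n_perm, 4L, dimnames = list(NULL, stats_names))
  })
  names(maxima) <- traits

  set.seed(seed)
  for (p in seq_len(n_perm)) {
    perm <- sample.int(n)
    for (tr in traits) {
      y <- pheno[[tr]][perm]
      f <- fam[perm]
      ok <- !is.na(y) & !is.na(f)
      null_ml <- NULL
      if (sum(ok) >= 6L && stats::var(y[ok]) > 1e-12) {
        nf <- fit_family_lmm(y[ok],
                             cbind(`(Intercept)` = rep(1, sum(ok))),
                             f[ok], REML = FALSE)
        null_ml <- list(logLik = nf$logLik, n = sum(ok))
      }
      mx <- c(mLOD = 0, aLOD = 0, dLOD = 0, iLOD = 0)
      for (m in seq_len(nrow(map))) {
        core <- .fit_locus_core(y, idx$x_a[, m], idx$x_d[, m],
                                idx$x_i[, m], f,
                                min_class_n = min_class_n,
                                null_ml = null_ml, estimates = FALSE)
        if (core$status == "ok") mx <- pmax(mx, core$lods)
      }
      maxima[[tr]][p, ] <- mx
    }
  }

  k <- max(1L, ceiling((1 - alpha) * n_perm))
  genomewide <- lapply(maxima, function(mm) {
    apply(mm, 2L, function(v) sort(v)[k])
  })
  out <- list(genomewide = genomewide, maxima = maxima, alpha = alpha,
              n_perm = as.integer(n_perm), pointwise_lod = pointwise_lod,
              seed = as.integer(seed))
  class(out) <- "threshold_set"
  out
}

#' Write / read a threshold set as JSON
#'
#' Serialises the genome-wide thresholds (per trait, per statistic),
#' alpha, n_perm, pointwise_lod and seed. The raw permutation maxima
#' are not serialised.
#'
#' @param thresholds a `threshold_set`.
#' @param path file path.
#' @export
write_thresholds_json <- function(thresholds, path) {
  obj <- list(genomewide = lapply(thresholds$genomewide, as.list),
              alpha = thresholds$alpha, n_perm = thresholds$n_perm,
              pointwise_lod = thresholds$pointwise_lod,
              seed = thresholds$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(genomewide = lapply(obj$genomewide, unlist),
              maxima = NULL, alpha = obj$alpha,
              n_perm = as.integer(obj$n_perm),
              pointwise_lod = obj$pointwise_lod,
              seed = as.integer(obj$seed))
  class(out) <- "threshold_set"
  out
}

## cluster sorted cM positions: new cluster when the gap to the previous
## marked position exceeds the merge window
.cluster_positions <- function(pos_sorted, merge_window) {
  cl <- integer(length(pos_sorted))
  cur <- 1L
  cl[1L] <- 1L
  for (j in seq_along(pos_sorted)[-1L]) {
    if (pos_sorted[j] - pos_sorted[j - 1L] > merge_window) cur <- cur + 1L
    cl[j] <- cur
  }
  cl
}

#' Call QTL from a scan and permutation thresholds
#'
#' A (trait, marker) is marked when any of the four statistics reaches
#' its genome-wide threshold for that trait. Marked markers on the same
#' chromosome within `merge_window` cM of each other are merged into
#' one locus; the locus peak is the marker carrying the largest
#' significant statistic (ties break to the smaller cM), and the trait
#' carrying it is the locus's primary trait. Every other trait whose
#' pointwise LOD (any statistic) reaches `pointwise_lod` at the peak
#' marker is attached with a "pointwise" flag — the pleiotropy rule.
#' Loci are named `Mc<chromosome>.<k>` in map order within chromosome.
#'
#' @param scan an `adi_scan`.
#' @param thresholds a `threshold_set` covering the scanned traits.
#' @param merge_window cM window for merging significant markers
#'   (default 20).
#' @param pointwise_lod pointwise cutoff for pleiotropy (default taken
#'   from `thresholds`).
#' @param ci_drop LOD drop defining the support interval (default 1).
#' @return List of class `qtl_calls` with `loci` (one row per QTL:
#'   name, chromosome, peak marker/positions, support interval, primary
#'   trait and statistic) and `effects` (one row per QTL x attached
#'   trait with estimates, LODs, per-statistic genome-wide flags and
#'   the significance level, "genomewide" or "pointwise").
#' @export
call_qtl <- function(scan, thresholds, merge_window = 20,
                     pointwise_lod = NULL, ci_drop = 1) {
  if (is.null(pointwise_lod)) pointwise_lod <- thresholds$pointwise_lod
  stats_names <- c("mLOD", "aLOD", "dLOD", "iLOD")
  usable <- scan[scan$status == "ok", , drop = FALSE]
  missing_tr <- setdiff(unique(usable$trait), names(thresholds$genomewide))
  if (length(missing_tr) > 0L) {
    stop("no thresholds for trait(s): ", paste(missing_tr, collapse = ", "))
  }

  ## mark genome-wide significant (trait, marker) rows
  marked <- list()
  for (ri in seq_len(nrow(usable))) {
    row <- usable[ri, ]
    thr <- thresholds$genomewide[[row$trait]]
    sig <- vapply(stats_names, function(s) row[[s]] >= thr[[s]], logical(1))
    if (any(sig)) {
      marked[[length(marked) + 1L]] <- data.frame(
        trait = row$trait, marker_id = row$marker_id,
        chromosome = row$chromosome, position_cM = row$position_cM,
        best_stat = stats_names[sig][which.max(unlist(row[stats_names[sig]]))],
        best_lod = max(unlist(row[stats_names[sig]])),
        stringsAsFactors = FALSE)
    }
  }
  empty <- list(loci = data.frame(), effects = data.frame())
  class(empty) <- "qtl_calls"
  if (length(marked) == 0L) return(empty)
  marked <- do.call(rbind, marked)

  loci <- list()
  effects <- list()
  for (chr in sort(unique(marked$chromosome))) {
    sub <- marked[marked$chromosome == chr, , drop = FALSE]
    pos <- sort(unique(sub$position_cM))
    cl_of_pos <- .cluster_positions(pos, merge_window)
    for (cl in unique(cl_of_pos)) {
      cl_pos <- pos[cl_of_pos == cl]
      rows <- sub[sub$position_cM %in% cl_pos, , drop = FALSE]
      ## peak: largest significant statistic, tie -> smaller cM
      ord <- order(-rows$best_lod, rows$position_cM)
      peak <- rows[ord[1L], ]
      ci <- support_interval(scan, peak$trait, peak$marker_id,
                             statistic = peak$best_stat, drop = ci_drop)
      loci[[length(loci) + 1L]] <- data.frame(
        chromosome = chr, peak_marker = peak$marker_id,
        peak_cM = peak$position_cM,
        ci_lo_cM = ci[1L], ci_hi_cM = ci[2L],
        primary_trait = peak$trait, peak_statistic = peak$best_stat,
        peak_lod = peak$best_lod, stringsAsFactors = FALSE)
      ## traits attached to this locus
      gw_traits <- unique(rows$trait)
      at_peak <- scan[scan$marker_id == peak$marker_id &
                        scan$status == "ok", , drop = FALSE]
      for (tr in unique(at_peak$trait)) {
        prow <- at_peak[at_peak$trait == tr, ][1L, ]
        thr <- thresholds$genomewide[[tr]]
        gw_flags <- vapply(stats_names,
                           function(s) prow[[s]] >= thr[[s]], logical(1))
        pw_flags <- vapply(stats_names,
                           function(s) prow[[s]] >= pointwise_lod,
                           logical(1))
        level <- if (tr %in% gw_traits) "genomewide"
                 else if (any(pw_flags)) "pointwise"
                 else NA_character_
        if (is.na(level)) next
        effects[[length(effects) + 1L]] <- data.frame(
          chromosome = chr, peak_marker = peak$marker_id, trait = tr,
          level = level,
          a = prow$a, d = prow$d, i = prow$i,
          mLOD = prow$mLOD, aLOD = prow$aLOD, dLOD = prow$dLOD,
          iLOD = prow$iLOD,
          mLOD_sig = gw_flags[["mLOD"]], aLOD_sig = gw_flags[["aLOD"]],
          dLOD_sig = gw_flags[["dLOD"]], iLOD_sig = gw_flags[["iLOD"]],
          mLOD_pw = pw_flags[["mLOD"]], aLOD_pw = pw_flags[["aLOD"]],
          dLOD_pw = pw_flags[["dLOD"]], iLOD_pw = pw_flags[["iLOD"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  loci <- name_qtl(do.call(rbind, loci))
  effects <- do.call(rbind, effects)
  key <- paste(effects$chromosome, effects$peak_marker)
  lkey <- paste(loci$chromosome, loci$peak_marker)
  effects <- cbind(name = loci$name[match(key, lkey)], effects)
  ## primary trait first within each locus, then by LOD
  effects <- effects[order(match(effects$name, loci$name),
                           effects$level != "genomewide",
                           -effects$mLOD), , drop = FALSE]
  rownames(effects) <- NULL
  out <- list(loci = loci, effects = effects)
  class(out) <- "qtl_calls"
  out
}

#' LOD-drop support interval
#'
#' The widest contiguous span of markers around the peak whose chosen
#' statistic stays within `drop` LOD of the peak value, on the peak's
#' chromosome. A single qualifying marker gives a zero-width interval.
#'
#' @param scan an `adi_scan`.
#' @param trait trait whose profile is used.
#' @param peak_marker marker id of the peak.
#' @param statistic one of "mLOD", "aLOD", "dLOD", "iLOD".
#' @param drop LOD units (default 1).
#' @return Numeric `c(lo_cM, hi_cM)`.
#' @export
support_interval <- function(scan, trait, peak_marker,
                             statistic = "mLOD", drop = 1) {
  prof <- scan[scan$trait == trait & scan$status == "ok", , drop = FALSE]
  pk <- prof[prof$marker_id == peak_marker, , drop = FALSE]
  if (nrow(pk) == 0L) stop("peak marker not in scan for trait ", trait)
  prof <- prof[prof$chromosome == pk$chromosome[1L], , drop = FALSE]
  prof <- prof[order(prof$position_cM), , drop = FALSE]
  j <- which(prof$marker_id == peak_marker)
  keep <- prof[[statistic]] >= pk[[statistic]][1L] - drop
  lo <- j
  while (lo > 1L && keep[lo - 1L]) lo <- lo - 1L
  hi <- j
  while (hi < nrow(prof) && keep[hi + 1L]) hi <- hi + 1L
  c(prof$position_cM[lo], prof$position_cM[hi])
}

#' Name QTL by chromosome and position
#'
#' Mouse-chromosome naming: `Mc<chr>.<k>` with `k` increasing with peak
#' position within each chromosome.
#'
#' @param loci data frame with `chromosome` and `peak_cM` columns.
#' @return The same data frame with a `name` column prepended.
#' @export
name_qtl <- function(loci) {
  if (is.null(loci) || nrow(loci) == 0L) {
    return(cbind(name = character(0), loci))
  }
  loci <- loci[order(loci$chromosome, loci$peak_cM), , drop = FALSE]
  k <- stats::ave(loci$peak_cM, loci$chromosome,
                  FUN = function(v) seq_along(v))
  loci <- cbind(name = sprintf("Mc%d.%d", loci$chromosome, as.integer(k)),
                loci)
  rownames(loci) <- NULL
  loci
}

#' Replay QTL grouping on a flagged effect table
#'
#' Applies the caller's grouping and naming logic to a table of
#' (trait, chromosome, position) rows already flagged significant —
#' e.g. a published effect table whose boldface encodes significance —
#' without recomputing any statistic. Rows with no flag set are
#' ignored.
#'
#' @param flagged data frame with columns `trait`, `chromosome`,
#'   `pos_cM` and logical `mLOD_sig`, `aLOD_sig`, `dLOD_sig`,
#'   `iLOD_sig`.
#' @param merge_window cM merge window (default 20).
#' @return Data frame of loci with `name`, `chromosome`, `peak_cM` and
#'   `n_traits` (distinct traits attached to the locus).
#' @export
qtl_from_flags <- function(flagged, merge_window = 20) {
  sig <- flagged$mLOD_sig | flagged$aLOD_sig | flagged$dLOD_sig |
    flagged$iLOD_sig
  marked <- flagged[sig, , drop = FALSE]
  loci <- list()
  for (chr in sort(unique(marked$chromosome))) {
    sub <- marked[marked$chromosome == chr, , drop = FALSE]
    pos <- sort(unique(sub$pos_cM))
    cl_of_pos <- .cluster_positions(pos, merge_window)
    for (cl in unique(cl_of_pos)) {
      cl_pos <- pos[cl_of_pos == cl]
      rows <- sub[sub$pos_cM %in% cl_pos, , drop = FALSE]
      loci[[length(loci) + 1L]] <- data.frame(
        chromosome = chr, peak_cM = min(cl_pos),
        n_traits = length(unique(rows$trait)), stringsAsFactors = FALSE)
    }
  }
  if (length(loci) == 0L) {
    return(cbind(name = character(0),
                 data.frame(chromosome = integer(0), peak_cM = numeric(0),
                            n_traits = integer(0))))
  }
  name_qtl(do.call(rbind, loci))
}
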