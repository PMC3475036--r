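#' Configuration for a reciprocal two-line cross
#'
#' Describes the mating scheme of an F0 to F3 intercross of two inbred
#' lines (alleles A and B). Two reciprocal F0 pairs (A sire x B dam and
#' B sire x A dam) found the cross; F1 animals are mated in reciprocal
#' pairs to produce the F2; F3 families come from random non-sibling F2
#' pairings.
#'
#' @param n_f2 number of F2 animals (default 94).
#' @param n_f3 number of F3 animals (default 345).
#' @param n_f3_analyzable number of F3 flagged analyzable, emulating
#'   loss of some animals to genotyping errors (default 331).
#' @param n_f1_per_cross F1 pups per reciprocal F0 pair; at least two of
#'   each sex are needed to form the two reciprocal F1 pairs (default 4).
#' @param n_f1_pairs number of F1 mating pairs producing the F2
#'   (default 2, one per cross direction).
#' @param f3_litter_size nominal F3 family size; the number of F2 pairs
#'   is `ceiling(n_f3 / f3_litter_size)` (default 7).
#' @return A list of class `cross_config`.
#' @export
cross_config <- function(n_f2 = 94L, n_f3 = 345L, n_f3_analyzable = 331L,
                         n_f1_per_cross = 4L, n_f1_pairs = 2L,
                         f3_litter_size = 7L) {
  cfg <- list(n_f2 = as.integer(n_f2), n_f3 = as.integer(n_f3),
              n_f3_analyzable = as.integer(n_f3_analyzable),
              n_f1_per_cross = as.integer(n_f1_per_cross),
              n_f1_pairs = as.integer(n_f1_pairs),
              f3_litter_size = as.integer(f3_litter_size))
  if (any(unlist(cfg) < 0L)) stop("cross_config sizes must be non-negative")
  if (cfg$n_f3_analyzable > cfg$n_f3) {
    stop("n_f3_analyzable cannot exceed n_f3")
  }
  class(cfg) <- "cross_config"
  cfg
}

#' Simulate a reciprocal-cross pedigree
#'
#' Builds the F0-F3 pedigree of a two-line reciprocal intercross. F0
#' founders are inbred (line A or B); the two cross directions are
#' A sire x B dam and B sire x A dam. F1 animals alternate sex within
#' each litter so both reciprocal F1 pairs can be formed. F2 families
#' are assigned round-robin to the F1 pairs; F3 families come from
#' random non-sibling F2 pairings (falling back to any distinct
#' opposite-sex pair when no non-sibling pair exists). A random subset
#' of F3 is flagged non-analyzable.
#'
#' Each individual carries `grandmaternal_line`, the founder line of its
#' matriline (the dam's `grandmaternal_line`, starting from the F0 dam's
#' line), which records the direction of cross it descends from.
#'
#' @param config a [cross_config()].
#' @param seed integer seed controlling mate choice and the analyzable
#'   subset.
#' @return A data frame of class `pedigree` with columns `id`, `sire`,
#'   `dam`, `sex` ("male"/"female"), `generation` ("F0".."F3"),
#'   `founder_line` (F0 only, else NA), `grandmaternal_line`,
#'   `family_id` (sire:dam pair, NA for F0) and `analyzable` (logical).
#' @export
simulate_pedigree <- function(config = cross_config(), seed = 1L) {
  set.seed(seed)
  rows <- list()
  add <- function(id, sire, dam, sex, generation, founder_line, gml) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, sire = sire, dam = dam, sex = sex, generation = generation,
      founder_line = founder_line, grandmaternal_line = gml,
      stringsAsFactors = FALSE)
  }

  ## F0: two reciprocal pairs
  add("F0_A_m1", NA, NA, "male",   "F0", "A", "A")
  add("F0_B_f1", NA, NA, "female", "F0", "B", "B")
  add("F0_B_m1", NA, NA, "male",   "F0", "B", "B")
  add("F0_A_f1", NA, NA, "female", "F0", "A", "A")
  f0_pairs <- list(c("F0_A_m1", "F0_B_f1"), c("F0_B_m1", "F0_A_f1"))

  ## F1: n_f1_per_cross pups per F0 pair, alternating sex
  f1 <- list()
  for (p in seq_along(f0_pairs)) {
    sire <- f0_pairs[[p]][1]
    dam <- f0_pairs[[p]][2]
    dam_line <- if (dam == "F0_B_f1") "B" else "A"
    for (k in seq_len(config$n_f1_per_cross)) {
      sex <- if (k %% 2L == 1L) "male" else "female"
      id <- sprintf("F1_%d_%d", p, k)
      add(id, sire, dam, sex, "F1", NA, dam_line)
      f1[[length(f1) + 1L]] <- list(id = id, sex = sex, cross = p)
    }
  }
  f1 <- do.call(rbind, lapply(f1, as.data.frame))

  ## F1 mating pairs: reciprocal by construction (male from one cross
  ## direction with a female from the other when both exist)
  if (config$n_f2 > 0L) {
    males <- f1[f1$sex == "male", , drop = FALSE]
    females <- f1[f1$sex == "female", , drop = FALSE]
    if (nrow(males) == 0L || nrow(females) == 0L) {
      stop("cannot produce F2: no F1 of one sex")
    }
    n_pairs <- min(config$n_f1_pairs, nrow(males), nrow(females))
    pair_sire <- character(n_pairs)
    pair_dam <- character(n_pairs)
    for (k in seq_len(n_pairs)) {
      ## alternate the sire's cross direction so the F1 pairs are
      ## reciprocal and both grandmaternal lines are represented
      want_cross <- ((k - 1L) %% 2L) + 1L
      mpool <- males[males$cross == want_cross, , drop = FALSE]
      if (nrow(mpool) == 0L) mpool <- males
      m <- mpool[((k - 1L) %/% 2L) %% nrow(mpool) + 1L, ]
      opp <- females[females$cross != m$cross, , drop = FALSE]
      pool <- if (nrow(opp) > 0L) opp else females
      f <- pool[((k - 1L) %/% 2L) %% nrow(pool) + 1L, ]
      pair_sire[k] <- as.character(m$id)
      pair_dam[k] <- as.character(f$id)
    }
    gml_of <- function(id) {
      i <- vapply(rows, function(r) r$id == id, logical(1))
      rows[[which(i)]]$grandmaternal_line
    }
    for (k in seq_len(config$n_f2)) {
      ## pair index advances every two pups so each family gets both sexes
      p <- ((k - 1L) %/% 2L) %% n_pairs + 1L
      add(sprintf("F2_%03d", k), pair_sire[p], pair_dam[p],
          if (k %% 2L == 1L) "male" else "female", "F2", NA,
          gml_of(pair_dam[p]))
    }
  }

  ped <- do.call(rbind, rows)

  ## F3: random non-sibling F2 pairs, litters of ~f3_litter_size
  if (config$n_f3 > 0L) {
    f2 <- ped[ped$generation == "F2", , drop = FALSE]
    males <- f2[f2$sex == "male", , drop = FALSE]
    females <- f2[f2$sex == "female", , drop = FALSE]
    if (nrow(males) == 0L || nrow(females) == 0L) {
      stop("cannot produce F3: no F2 of one sex")
    }
    n_fam <- max(1L, ceiling(config$n_f3 / config$f3_litter_size))
    sizes <- rep(config$n_f3 %/% n_fam, n_fam)
    rem <- config$n_f3 %% n_fam
    if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    k <- 0L
    f3_rows <- list()
    for (fam in seq_len(n_fam)) {
      sire <- males[sample.int(nrow(males), 1L), ]
      nonsib <- females[!(females$sire == sire$sire &
                            females$dam == sire$dam), , drop = FALSE]
      pool <- if (nrow(nonsib) > 0L) nonsib else females
      dam <- pool[sample.int(nrow(pool), 1L), ]
      for (j in seq_len(sizes[fam])) {
        k <- k + 1L
        f3_rows[[k]] <- data.frame(
          id = sprintf("F3_%03d", k), sire = sire$id, dam = dam$id,
          sex = if (j %% 2L == 1L) "female" else "male",
          generation = "F3", founder_line = NA_character_,
          grandmaternal_line = dam$grandmaternal_line,
          stringsAsFactors = FALSE)
      }
    }
    ped <- rbind(ped, do.call(rbind, f3_rows))
  }

  ped$family_id <- ifelse(is.na(ped$sire), NA_character_,
                          paste(ped$sire, ped$dam, sep = ":"))
  ped$analyzable <- TRUE
  f3_idx <- which(ped$generation == "F3")
  n_drop <- length(f3_idx) - min(config$n_f3_analyzable, length(f3_idx))
  if (n_drop > 0L) {
    ped$analyzable[sample(f3_idx, n_drop)] <- FALSE
  }
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate a pedigree
#'
#' Checks topological order (parents precede offspring), parent sexes,
#' generation steps of exactly one, and founder conventions.
#'
#' @param ped a `pedigree` data frame.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_pedigree <- function(ped) {
  gen_num <- c(F0 = 0L, F1 = 1L, F2 = 2L, F3 = 3L)
  if (anyDuplicated(ped$id)) stop("duplicated individual ids")
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$id
  for (i in seq_len(nrow(ped))) {
    r <- ped[i, ]
    if (r$generation == "F0") {
      if (!is.na(r$sire) || !is.na(r$dam)) stop("F0 must have no parents")
      if (is.na(r$founder_line)) stop("F0 must have a founder_line")
    } else {
      if (is.na(r$sire) || is.na(r$dam)) {
        stop("non-founder ", r$id, " lacks a parent")
      }
      for (p in c(r$sire, r$dam)) {
        if (is.na(pos[p])) stop("parent ", p, " not in pedigree")
        if (pos[p] >= i) stop("pedigree not topologically ordered at ", r$id)
      }
      if (ped$sex[pos[r$sire]] != "male") stop("sire of ", r$id, " not male")
      if (ped$sex[pos[r$dam]] != "female") stop("dam of ", r$id, " not female")
      for (p in c(r$sire, r$dam)) {
        if (gen_num[ped$generation[pos[p]]] != gen_num[r$generation] - 1L) {
          stop("parent generation mismatch at ", r$id)
        }
      }
    }
  }
  invisible(TRUE)
}

#' Read / write a pedigree as tab-separated text
#'
#' Columns: id, sire, dam, sex, generation, grandmaternal_line,
#' analyzable (and founder_line, kept for round-tripping).
#'
#' @param path file path.
#' @return `read_pedigree_tsv` returns a `pedigree`.
#' @export
read_pedigree_tsv <- function(path) {
  ped <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  ped$analyzable <- as.logical(ped$analyzable)
  ped$family_id <- ifelse(is.na(ped$sire), NA_character_,
                          paste(ped$sire, ped$dam, sep = ":"))
  ped <- ped[c("id", "sire", "dam", "sex", "generation", "founder_line",
               "grandmaternal_line", "family_id", "analyzable")]
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' @rdname read_pedigree_tsv
#' @param ped a `pedigree`.
#' @export
write_pedigree_tsv <- function(ped, path) {
  cols <- c("id", "sire", "dam", "sex", "generation", "founder_line",
            "grandmaternal_line", "analyzable")
  utils::write.table(as.data.frame(ped)[cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
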