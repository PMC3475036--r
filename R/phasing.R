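#' Recover ordered genotypes by pedigree transmission
#'
#' Reconstructs parent-of-origin (ordered) genotypes from unordered
#' genotype calls plus the pedigree, marker by marker:
#'
#' 1. a homozygote is ordered trivially;
#' 2. a heterozygote with at least one homozygous parent is ordered by
#'    that parent's forced contribution;
#' 3. a heterozygote whose parents are both heterozygous is, when
#'    `use_flanking` is on, given the order that minimises
#'    recombinations against the nearest already-phased flanking
#'    markers in the same parental gamete (ties stay unresolved);
#'    otherwise it stays missing.
#'
#' Entries where no order is Mendelian-consistent with the parents are
#' recorded as conflicts and left missing. Rules 1-2 are exact; the
#' flanking rule is a heuristic that can mis-order a heterozygote when
#' a crossover falls between the marker and its nearest resolved
#' neighbour, so it trades a small error rate for a higher resolved
#' fraction.
#'
#' @param unordered character matrix of codes "A"/"H"/"B" (individuals
#'   x markers, rownames = ids, colnames = marker ids).
#' @param ped a `pedigree`; every non-founder in `unordered` must have
#'   both parents present in the matrix.
#' @param use_flanking enable rule 3 (default FALSE).
#' @param map `genetic_map`, required when `use_flanking = TRUE` (for
#'   chromosome assignment of markers).
#' @return List of class `phase_result`: `ordered` (matrix of
#'   AA/AB/BA/BB or NA), `resolved_fraction` (resolved entries over
#'   non-missing unordered entries) and `conflicts` (data frame of
#'   individual, marker, description).
#' @export
phase_by_transmission <- function(unordered, ped, use_flanking = FALSE,
                                  map = NULL) {
  if (use_flanking && is.null(map)) {
    stop("use_flanking requires the genetic map")
  }
  ids <- rownames(unordered)
  ped <- ped[ped$id %in% ids, , drop = FALSE]
  ordered <- matrix(NA_character_, nrow(unordered), ncol(unordered),
                    dimnames = dimnames(unordered))
  conflicts <- list()
  note_conflict <- function(id, marker, what) {
    conflicts[[length(conflicts) + 1L]] <<- data.frame(
      individual = id, marker = marker, description = what,
      stringsAsFactors = FALSE)
  }
  ## can this parent (unordered code) transmit the allele?
  can_give <- function(parent_code, allele) {
    is.na(parent_code) | parent_code == "H" | parent_code == allele
  }

  for (r in seq_len(nrow(ped))) {
    id <- ped$id[r]
    g <- unordered[id, ]
    if (ped$generation[r] == "F0") {
      line <- ped$founder_line[r]
      bad <- !is.na(g) & g != line
      for (m in which(bad)) {
        note_conflict(id, colnames(unordered)[m],
                      "founder genotype inconsistent with line")
      }
      ordered[id, !is.na(g) & !bad] <- paste0(line, line)
      next
    }
    sire <- ped$sire[r]
    dam <- ped$dam[r]
    if (!(sire %in% ids) || !(dam %in% ids)) {
      stop("parents of ", id, " are absent from the genotype matrix")
    }
    gs <- unordered[sire, ]
    gd <- unordered[dam, ]
    res <- rep(NA_character_, length(g))

    hom <- !is.na(g) & g %in% c("A", "B")
    ok_hom <- hom & can_give(gs, g) & can_give(gd, g)
    res[ok_hom] <- paste0(g[ok_hom], g[ok_hom])
    for (m in which(hom & !ok_hom)) {
      note_conflict(id, colnames(unordered)[m],
                    "homozygote not transmissible by a parent")
    }

    het <- !is.na(g) & g == "H"
    ## forced paternal allele from a homozygous sire
    sire_hom <- het & !is.na(gs) & gs %in% c("A", "B")
    dam_hom <- het & !is.na(gd) & gd %in% c("A", "B")
    other <- function(al) ifelse(al == "A", "B", "A")
    for (m in which(het)) {
      pat <- NA_character_
      mat <- NA_character_
      if (sire_hom[m]) pat <- gs[m]
      if (dam_hom[m]) mat <- gd[m]
      if (!is.na(pat) && !is.na(mat) && pat == mat) {
        note_conflict(id, colnames(unordered)[m],
                      "heterozygote impossible from homozygous parents")
        next
      }
      if (!is.na(pat)) {
        res[m] <- paste0(pat, other(pat))
      } else if (!is.na(mat)) {
        res[m] <- paste0(other(mat), mat)
      }
    }
    ordered[id, ] <- res
  }

  if (use_flanking) {
    map <- map[match(colnames(unordered), map$marker_id), , drop = FALSE]
    pos <- map$position_cM
    chr <- map$chromosome
    ## haplotype views of the transmission-pass result: column k of
    ## allele1/allele2 is an individual's paternal/maternal allele
    allele1 <- substr(ordered, 1L, 1L)  # substr(NA) stays NA
    allele2 <- substr(ordered, 2L, 2L)

    ## which of the parent's two haplotypes carried the child's
    ## gamete allele at marker m? Informative only where the parent's
    ## order is resolved and the parent is heterozygous.
    hap_source <- function(child_allele, par1, par2) {
      ifelse(is.na(child_allele) | is.na(par1) | par1 == par2, NA,
             ifelse(child_allele == par1, 1L, 2L))
    }

    for (r in seq_len(nrow(ped))) {
      if (ped$generation[r] == "F0") next
      id <- ped$id[r]
      unres <- which(!is.na(unordered[id, ]) & unordered[id, ] == "H" &
                       is.na(ordered[id, ]))
      if (length(unres) == 0L) next
      sire <- ped$sire[r]
      dam <- ped$dam[r]
      ## transmitted-haplotype tracks along both gametes
      src_pat <- hap_source(allele1[id, ], allele1[sire, ], allele2[sire, ])
      src_mat <- hap_source(allele2[id, ], allele1[dam, ], allele2[dam, ])

      for (m in unres) {
        same_chr <- which(chr == chr[m])
        ## candidate orderings: paternal allele P, maternal allele the other
        cand <- c("A", "B")
        cost <- c(0L, 0L)
        info <- c(FALSE, FALSE)
        for (ci in 1:2) {
          P <- cand[ci]
          Q <- if (P == "A") "B" else "A"
          ## gamete-wise: which parent haplotype would carry this allele
          for (side in 1:2) {
            par <- if (side == 1L) sire else dam
            al <- if (side == 1L) P else Q
            src <- if (side == 1L) src_pat else src_mat
            p1 <- allele1[par, m]; p2 <- allele2[par, m]
            if (is.na(p1) || p1 == p2) next  # parent uninformative at m
            h_m <- if (al == p1) 1L else 2L
            anchors <- same_chr[!is.na(src[same_chr]) & same_chr != m]
            if (length(anchors) == 0L) next
            left <- anchors[pos[anchors] < pos[m]]
            right <- anchors[pos[anchors] > pos[m]]
            for (a in c(if (length(left)) left[which.max(pos[left])],
                        if (length(right)) right[which.min(pos[right])])) {
              info[ci] <- TRUE
              if (src[a] != h_m) cost[ci] <- cost[ci] + 1L
            }
          }
        }
        if (!any(info)) next
        if (cost[1L] == cost[2L]) next  # tie: stays unresolved
        P <- cand[which.min(cost)]
        ordered[id, m] <- paste0(P, if (P == "A") "B" else "A")
      }
    }
  }

  conflicts <- if (length(conflicts)) do.call(rbind, conflicts) else
    data.frame(individual = character(0), marker = character(0),
               description = character(0))
  out <- list(
    ordered = structure(ordered, class = c("ordered_geno", class(ordered))),
    resolved_fraction = sum(!is.na(ordered)) / max(1L, sum(!is.na(unordered))),
    conflicts = conflicts)
  class(out) <- "phase_result"
  out
}
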