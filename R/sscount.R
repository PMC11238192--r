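#' Compute the ss-count profile of a structure ensemble
#'
#' The ss-count of a position is the number of structures in the ensemble
#' in which that position is single-stranded (unpaired). A position
#' unpaired in every structure of a 30-structure ensemble has ss-count 30;
#' one paired in every structure has ss-count 0. `ss_fraction` normalizes
#' by the ensemble size so profiles from ensembles of different sizes are
#' comparable.
#'
#' @param ensemble A `structure_ensemble`.
#' @param offset 0-based offset of the folded window into its parent
#'   transcript (0 when folding a whole transcript). Carried through to
#'   downstream coordinate reconciliation.
#' @param allele Optional allele label ("wt"/"mut") carried as metadata.
#' @return Object of class `ss_count_profile`: `ss_count` (integer per
#'   position), `n_structures`, `ss_fraction`, `sequence`, `offset`,
#'   `allele`.
#' @export
compute_ss_count <- function(ensemble, offset = 0L, allele = NA_character_) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  n <- nchar(ensemble$sequence)
  ss <- integer(n)
  for (s in ensemble$structures) ss <- ss + (s$partner == 0L)
  structure(list(ss_count = ss,
                 n_structures = ensemble$n_structures,
                 ss_fraction = ss / ensemble$n_structures,
                 sequence = ensemble$sequence,
                 offset = as.integer(offset),
                 allele = allele),
            class = "ss_count_profile")
}

#' Classify per-position accessibility from an ss-count profile
#'
#' Three-way partition of positions by `ss_fraction`: open (at or above
#' `t_open`), closed (at or below `t_closed`), semi-open in between. The
#' defaults are symmetric tertiles, reproducing the three-color
#' (green/yellow/red) heatmap semantics.
#'
#' @param profile An [compute_ss_count()] result.
#' @param t_open,t_closed Thresholds on `ss_fraction`, with
#'   `t_closed < t_open`, both in \[0, 1\].
#' @return Object of class `accessibility_map`: `class` (factor-like
#'   character vector "open"/"semi_open"/"closed"), `ss_fraction`,
#'   `thresholds`, `offset`, `allele`.
#' @export
classify_accessibility <- function(profile, t_open = 2 / 3, t_closed = 1 / 3) {
  stopifnot(inherits(profile, "ss_count_profile"))
  if (!(t_closed < t_open) || t_open > 1 || t_closed < 0) {
    stop("need 0 <= t_closed < t_open <= 1", call. = FALSE)
  }
  fr <- profile$ss_fraction
  cls <- ifelse(fr >= t_open, "open", ifelse(fr <= t_closed, "closed", "semi_open"))
  structure(list(class = cls, ss_fraction = fr,
                 thresholds = c(t_open = t_open, t_closed = t_closed),
                 offset = profile$offset, allele = profile$allele),
            class = "accessibility_map")
}

#' Differential accessibility between the mutant and wild-type alleles
#'
#' Reconciles a mutant-allele and a wild-type-allele accessibility map
#' through the exon coordinate map and reports, in mutant coordinates:
#' `mut_accessible_wt_closed`, the positions open or semi-open in the
#' mutant whose wild-type image is closed (where mixmer RNA blocks
#' belong), and `open_in_both`, the positions open in both alleles
#' (mismatch candidates), optionally restricted to a named exon.
#'
#' @param mut_map,wt_map [classify_accessibility()] results computed on
#'   mutant and wild-type windows.
#' @param pair The [build_junction_pair()] the windows were cut from.
#' @param region Optional exon id; restricts `open_in_both` to that exon.
#' @return Object of class `differential_map` with the two 0-based
#'   mutant-coordinate position sets, plus `margin` (mutant minus
#'   wild-type `ss_fraction`, named by mutant position) over the
#'   reconciled overlap.
#' @export
differential_accessibility <- function(mut_map, wt_map, pair, region = NULL) {
  stopifnot(inherits(mut_map, "accessibility_map"),
            inherits(wt_map, "accessibility_map"),
            inherits(pair, "transcript_pair"))
  mut_pos <- mut_map$offset + seq_along(mut_map$class) - 1L  # 0-based mut coords
  wt_img <- map_mut_to_wt(pair, mut_pos)
  wt_lo <- wt_map$offset
  wt_hi <- wt_map$offset + length(wt_map$class) - 1L
  inside <- wt_img >= wt_lo & wt_img <= wt_hi
  if (!any(inside)) {
    stop("the two windows do not overlap after coordinate mapping", call. = FALSE)
  }
  mp <- mut_pos[inside]
  mc <- mut_map$class[inside]
  wc <- wt_map$class[wt_img[inside] - wt_lo + 1L]
  mfr <- mut_map$ss_fraction[inside]
  wfr <- wt_map$ss_fraction[wt_img[inside] - wt_lo + 1L]

  diff_set <- mp[mc %in% c("open", "semi_open") & wc == "closed"]
  both_open <- mp[mc == "open" & wc == "open"]
  if (!is.null(region)) {
    ex <- pair$exons_mut[pair$exons_mut$id == region, ]
    if (nrow(ex) != 1L) stop("exon '", region, "' not present in the mutant transcript",
                             call. = FALSE)
    both_open <- both_open[both_open >= ex$start & both_open < ex$end]
  }
  margin <- mfr - wfr
  names(margin) <- mp
  structure(list(mut_accessible_wt_closed = diff_set,
                 open_in_both = both_open,
                 margin = margin,
                 region = region),
            class = "differential_map")
}

#' Export a heatmap-style accessibility table across window lengths
#'
#' One row per position of the shortest window, with the per-window-length
#' ss-counts and accessibility classes and a consensus class. The
#' consensus is the majority class across window lengths; ties resolve to
#' semi_open.
#'
#' @param profiles Named list of `ss_count_profile`s for the same allele,
#'   one per window length (names are used as column suffixes). All
#'   profiles must be positioned on the same parent transcript (their
#'   `offset`s reconcile the coordinates).
#' @param t_open,t_closed Classification thresholds (see
#'   [classify_accessibility()]).
#' @param path Optional TSV output path.
#' @return A data.frame with columns `position` (0-based parent
#'   coordinate), `base`, one `ss_count_<name>` and `class_<name>` pair
#'   per profile, and `consensus`.
#' @export
export_heatmap_table <- function(profiles, t_open = 2 / 3, t_closed = 1 / 3,
                                 path = NULL) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "ss_count_profile")))
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    names(profiles) <- vapply(profiles, function(p) as.character(nchar(p$sequence)),
                              character(1))
  }
  lo <- max(vapply(profiles, function(p) p$offset, integer(1)))
  hi <- min(vapply(profiles, function(p) p$offset + nchar(p$sequence) - 1L,
                   integer(1)))
  if (lo > hi) stop("profiles share no common positions", call. = FALSE)
  pos <- lo:hi
  ref <- profiles[[1L]]
  out <- data.frame(position = pos,
                    base = seq_chars(ref$sequence)[pos - ref$offset + 1L],
                    stringsAsFactors = FALSE)
  classes <- matrix(NA_character_, length(pos), length(profiles))
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    idx <- pos - p$offset + 1L
    cls <- classify_accessibility(p, t_open, t_closed)$class[idx]
    out[[paste0("ss_count_", names(profiles)[k])]] <- p$ss_count[idx]
    out[[paste0("class_", names(profiles)[k])]] <- cls
    classes[, k] <- cls
  }
  out$consensus <- apply(classes, 1L, function(cl) {
    tb <- table(cl)
    top <- names(tb)[tb == max(tb)]
    if (length(top) > 1L) "semi_open" else top
  })
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
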