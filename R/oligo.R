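SUGARS <- c("DNA", "OMe2", "MOE2", "LNA")
BRACKET_SUGAR <- c("[" = "OMe2", "<" = "MOE2", "{" = "LNA")
BRACKET_CLOSE <- c("[" = "]", "<" = ">", "{" = "}")

#' Construct an oligonucleotide design
#'
#' @param name Design label.
#' @param base Character vector of bases, 5' to 3' (A/C/G/T/U).
#' @param sugar Character vector: "DNA", "OMe2" (2'-O-methyl), "MOE2"
#'   (2'-O-methoxyethyl) or "LNA".
#' @param backbone Character vector, "PS" or "PO". Defaults to all-PS
#'   (standard for therapeutic gapmers).
#' @param category One of "gapmer", "mixmer", "mismatch_mixmer", "other";
#'   inferred from the chemistry run pattern when `NULL`.
#' @param mismatch_positions Integer vector of 1-based positions at which
#'   the design deliberately mismatches its target.
#' @param footprint Optional 0-based half-open interval `c(start, end)` of
#'   the intended target site on the mutant transcript.
#' @return Object of class `oligo_design`.
#' @export
oligo_design <- function(name, base, sugar, backbone = rep("PS", length(base)),
                         category = NULL, mismatch_positions = integer(0),
                         footprint = NULL) {
  base <- toupper(base)
  stopifnot(length(base) >= 1L, length(sugar) == length(base),
            length(backbone) == length(base),
            all(base %in% c("A", "C", "G", "T", "U")),
            all(sugar %in% SUGARS), all(backbone %in% c("PS", "PO")))
  # alphabet conventions: DNA uses T, 2'-OMe/2'-MOE use U, LNA permits both
  base[sugar == "DNA"] <- chartr("U", "T", base[sugar == "DNA"])
  base[sugar %in% c("OMe2", "MOE2")] <- chartr("T", "U", base[sugar %in% c("OMe2", "MOE2")])
  res <- data.frame(base = base, sugar = sugar, backbone = backbone,
                    stringsAsFactors = FALSE)
  if (is.null(category)) {
    category <- infer_category(res, mismatch_positions)
  }
  structure(list(name = name, residues = res, category = category,
                 mismatch_positions = as.integer(mismatch_positions),
                 footprint = footprint),
            class = "oligo_design")
}

#' @export
print.oligo_design <- function(x, ...) {
  cat(sprintf("oligo_design '%s' (%s, %d nt): %s\n", x$name, x$category,
              nrow(x$residues), serialize_oligo(x)))
  invisible(x)
}

#' @export
length.oligo_design <- function(x) nrow(x$residues)

# category from the chemistry run pattern: one internal DNA run flanked by
# non-DNA on both sides = gapmer; >= 2 DNA runs = mixmer
infer_category <- function(residues, mismatch_positions = integer(0)) {
  if (length(mismatch_positions) > 0L) return("mismatch_mixmer")
  r <- rle(residues$sugar == "DNA")
  ndna <- sum(r$values)
  if (ndna >= 2L) return("mixmer")
  if (ndna == 1L && length(r$values) >= 3L && !r$values[1] && !r$values[length(r$values)]) {
    return("gapmer")
  }
  "other"
}

#' Parse the bracket/asterisk ASO notation
#'
#' `[..]` marks a 2'-OMe block, `<..>` a 2'-MOE block, `{..}` an LNA
#' block; a base suffixed with `*` (or the Unicode asterisk operator) is a
#' PS-DNA residue. Whitespace and markdown bold markers (`**`) are
#' ignored. Brackets may not nest; every base needs either a bracket
#' context or a star.
#'
#' @param text Notation string.
#' @param name Design label.
#' @param mismatch_positions Passed through to [oligo_design()].
#' @return An `oligo_design`.
#' @examples
#' parse_oligo_notation("[CCACGCU] C*A*C*C*C*T*T*T* [GGCCCGA]", name = "2'-OMe-2")
#' @export
parse_oligo_notation <- function(text, name = "design",
                                 mismatch_positions = integer(0)) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- gsub("∗", "*", text)       # asterisk operator -> ASCII star
  x <- gsub("\\*\\*", "", x)           # markdown bold markers
  x <- gsub("[[:space:]]", "", x)
  ch <- seq_chars(x)
  base <- character(0); sugar <- character(0)
  context <- NA_character_  # open bracket char, or NA outside brackets
  i <- 1L
  while (i <= length(ch)) {
    c0 <- ch[i]
    if (c0 %in% names(BRACKET_SUGAR)) {
      if (!is.na(context)) stop("nested bracket '", c0, "' at offset ", i, call. = FALSE)
      context <- c0
      i <- i + 1L
    } else if (c0 %in% BRACKET_CLOSE) {
      if (is.na(context) || BRACKET_CLOSE[[context]] != c0) {
        stop("unbalanced closing bracket '", c0, "' at offset ", i, call. = FALSE)
      }
      context <- NA_character_
      i <- i + 1L
    } else if (grepl("[ACGTUacgtu]", c0)) {
      b <- toupper(c0)
      if (!is.na(context)) {
        base <- c(base, b); sugar <- c(sugar, BRACKET_SUGAR[[context]])
        i <- i + 1L
      } else if (i < length(ch) && ch[i + 1L] == "*") {
        base <- c(base, b); sugar <- c(sugar, "DNA")
        i <- i + 2L
      } else {
        stop("base '", b, "' at offset ", i,
             " has neither a bracket context nor a '*' star", call. = FALSE)
      }
    } else if (c0 == "*") {
      stop("stray '*' at offset ", i, call. = FALSE)
    } else {
      stop("unexpected character '", c0, "' at offset ", i, call. = FALSE)
    }
  }
  if (!is.na(context)) {
    stop("unbalanced opening bracket '", context, "'", call. = FALSE)
  }
  if (length(base) == 0L) stop("empty design", call. = FALSE)
  oligo_design(name, base, sugar, mismatch_positions = mismatch_positions)
}

#' Serialize a design to canonical bracket/asterisk notation
#'
#' Single spaces between chemistry runs; a `*` after every DNA base;
#' `[..]`, `<..>`, `{..}` for 2'-OMe, 2'-MOE and LNA runs.
#'
#' @param design An `oligo_design`.
#' @return Notation string; `parse_oligo_notation()` of it recovers the
#'   residues exactly.
#' @export
serialize_oligo <- function(design) {
  stopifnot(inherits(design, "oligo_design"))
  res <- design$residues
  if (nrow(res) == 0L) stop("empty design", call. = FALSE)
  r <- rle(res$sugar)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  chunks <- character(length(r$values))
  open <- c(OMe2 = "[", MOE2 = "<", LNA = "{")
  close <- c(OMe2 = "]", MOE2 = ">", LNA = "}")
  for (k in seq_along(r$values)) {
    bs <- res$base[starts[k]:stops[k]]
    if (r$values[k] == "DNA") {
      chunks[k] <- paste0(paste0(bs, "*"), collapse = "")
    } else {
      chunks[k] <- paste0(open[[r$values[k]]], paste(bs, collapse = ""),
                          close[[r$values[k]]])
    }
  }
  paste(chunks, collapse = " ")
}

#' GC content of a design, in percent
#'
#' @param design An `oligo_design`.
#' @return 100 * (#G + #C) / length, rounded to one decimal.
#' @export
gc_content <- function(design) {
  stopifnot(inherits(design, "oligo_design"))
  round(100 * mean(design$residues$base %in% c("G", "C")), 1)
}

# SantaLucia unified DNA nearest-neighbor parameters:
# dH kcal/mol, dS cal/(mol K), 5'->3' top-strand dinucleotide steps
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, TG = -22.7,
           GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Model-based melting temperature of a design against its RNA complement
#'
#' Nearest-neighbor two-state Tm on the base sequence (U read as T), with
#' salt correction and additive per-residue increments for the sugar
#' chemistries (modified riboses raise duplex stability). Designs shorter
#' than 8 nt fall back to the Wallace rule. The value is a model-based
#' analogue for comparing designs, not a reproduction of any external
#' calculator.
#'
#' @param design An `oligo_design`.
#' @param oligo_conc Total strand concentration, molar (default 0.25 uM).
#' @param na_conc Monovalent cation concentration, molar (default 50 mM).
#' @param increments Per-residue Tm increments (degrees C) by sugar.
#' @return Tm in degrees Celsius.
#' @export
melting_temperature <- function(design, oligo_conc = 0.25e-6, na_conc = 0.05,
                                increments = c(LNA = 3.0, MOE2 = 1.0, OMe2 = 0.7)) {
  stopifnot(inherits(design, "oligo_design"))
  if (oligo_conc <= 0 || na_conc <= 0) {
    stop("strand and salt concentrations must be positive", call. = FALSE)
  }
  b <- chartr("U", "T", design$residues$base)
  n <- length(b)
  if (n >= 8L) {
    steps <- paste0(b[-n], b[-1L])
    dH <- sum(NN_DH[steps]) +
      sum(ifelse(b[c(1L, n)] %in% c("G", "C"), 0.1, 2.3))
    dS <- sum(NN_DS[steps]) +
      sum(ifelse(b[c(1L, n)] %in% c("G", "C"), -2.8, 4.1))
    dS <- dS + 0.368 * (n - 1) * log(na_conc)
    tm <- 1000 * dH / (dS + 1.987 * log(oligo_conc / 4)) - 273.15
  } else {
    tm <- 2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
  }
  mods <- design$residues$sugar
  tm + sum(increments[mods[mods %in% names(increments)]])
}

#' DNA-run architecture and RNase-H competence of a design
#'
#' Lengths of the maximal consecutive PS-DNA runs, 5' to 3'. A design is
#' flagged RNase-H competent when its longest DNA run reaches `min_run`
#' (default 4 consecutive PS-DNA residues; configurable to 3 to admit
#' shorter-gap mixmers).
#'
#' @param design An `oligo_design`.
#' @param min_run Minimum run length for RNase-H competence.
#' @return List with `runs` (integer vector, possibly empty),
#'   `longest` and `rnaseh_competent`.
#' @export
dna_run_profile <- function(design, min_run = 4L) {
  stopifnot(inherits(design, "oligo_design"))
  is_gap <- design$residues$sugar == "DNA" & design$residues$backbone == "PS"
  r <- rle(is_gap)
  runs <- r$lengths[r$values]
  longest <- if (length(runs)) max(runs) else 0L
  list(runs = as.integer(runs), longest = as.integer(longest),
       rnaseh_competent = longest >= min_run)
}

#' Scan a transcript set for off-target binding sites
#'
#' Finds every ungapped alignment of the design's target site (the
#' reverse complement of the ASO, T/U-equivalent) against the forward
#' strand of each transcript with at most `max_mismatches` substitutions.
#' Hits overlapping the declared intended site are excluded.
#'
#' @param design An `oligo_design`.
#' @param transcripts Named character vector of transcript sequences, or a
#'   FASTA path.
#' @param max_mismatches 0, 1 or 2 substitutions.
#' @param intended Optional intended target, a list with `transcript`
#'   (name) and `start` (0-based): overlapping hits are dropped.
#' @return data.frame with columns `transcript`, `start` (0-based),
#'   `end` (half-open), `mismatches`.
#' @export
off_target_scan <- function(design, transcripts, max_mismatches = 0L,
                            intended = NULL) {
  stopifnot(inherits(design, "oligo_design"))
  if (!max_mismatches %in% 0:2) stop("max_mismatches must be 0, 1 or 2", call. = FALSE)
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts)) {
    transcripts <- read_transcripts_fasta(transcripts)
  }
  if (length(transcripts) == 0L) stop("empty transcript set", call. = FALSE)
  if (is.null(names(transcripts))) names(transcripts) <- paste0("tx", seq_along(transcripts))
  aso <- paste(design$residues$base, collapse = "")
  site <- reverse_complement(aso, alphabet = "DNA")
  subj <- Biostrings::DNAStringSet(chartr("U", "T", vapply(transcripts, normalize_rna,
                                                           character(1))))
  pat <- Biostrings::DNAString(site)
  hits <- Biostrings::vmatchPattern(pat, subj, max.mismatch = max_mismatches)
  out <- data.frame(transcript = character(0), start = integer(0),
                    end = integer(0), mismatches = integer(0),
                    stringsAsFactors = FALSE)
  for (k in seq_along(hits)) {
    rg <- hits[[k]]
    if (length(rg) == 0L) next
    s1 <- as.data.frame(rg)$start
    for (s in s1) {
      frag <- substr(as.character(subj[[k]]), s, s + nchar(site) - 1L)
      mm <- sum(seq_chars(frag) != seq_chars(site))
      out <- rbind(out, data.frame(transcript = names(transcripts)[k],
                                   start = s - 1L, end = s - 1L + nchar(site),
                                   mismatches = mm, stringsAsFactors = FALSE))
    }
  }
  if (!is.null(intended) && nrow(out) > 0L) {
    L <- nchar(site)
    keep <- !(out$transcript == intended$transcript &
                out$start < intended$start + L & out$end > intended$start)
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
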