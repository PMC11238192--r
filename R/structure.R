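#' Folding parameters for the baseline secondary-structure engine
#'
#' The baseline energy model scores each base pair by type (GC/CG, AU/UA,
#' GU/UG; more negative is more stable) and forbids pseudoknots and
#' hairpin loops shorter than `min_loop`. Sequences up to
#' `exhaustive_cutoff` nucleotides are folded exhaustively: the ensemble
#' is every valid structure within `epsilon` score units of the optimum.
#' Longer sequences are folded by seeded Boltzmann-weighted sampling of
#' `n_samples` structures (temperature `kT`, in score units), always
#' including the optimum.
#'
#' @param gc,au,gu Pair scores (score units, negative = stabilizing).
#' @param min_loop Minimum number of unpaired bases in a hairpin loop.
#' @param exhaustive_cutoff Maximum length for exhaustive enumeration.
#' @param epsilon Suboptimal energy band above the optimum (score units).
#' @param n_samples Sample size for long sequences.
#' @param seed Integer seed for the stochastic sampler (recorded in the
#'   ensemble).
#' @param kT Sampling temperature in score units.
#' @return A list of class `fold_params`.
#' @export
fold_params <- function(gc = -3, au = -2, gu = -1, min_loop = 3L,
                        exhaustive_cutoff = 25L, epsilon = 2,
                        n_samples = 30L, seed = 101L, kT = 1) {
  stopifnot(gc < 0, au < 0, gu < 0, min_loop >= 0, epsilon >= 0,
            n_samples >= 1, kT > 0)
  structure(list(gc = gc, au = au, gu = gu, min_loop = as.integer(min_loop),
                 exhaustive_cutoff = as.integer(exhaustive_cutoff),
                 epsilon = epsilon, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), kT = kT),
            class = "fold_params")
}

# n x n matrix of pair scores; NA where the two bases cannot pair
pair_score_matrix <- function(bases, params) {
  key <- c(GC = params$gc, CG = params$gc, AU = params$au, UA = params$au,
           GU = params$gu, UG = params$gu)
  n <- length(bases)
  dimer <- outer(bases, bases, paste0)
  m <- matrix(key[dimer], n, n)
  m
}

#' A single secondary structure
#'
#' @param partner Integer vector: `partner[i]` is the 1-based pairing
#'   partner of position i, or 0 if unpaired.
#' @param sequence The RNA sequence the structure belongs to.
#' @param energy Structure score; computed from `params` when `NULL`.
#' @param params A [fold_params()] object used for validation/scoring.
#' @param validate Check the structure invariants (involution, nestedness,
#'   minimum loop, allowed pair types).
#' @return Object of class `secondary_structure`.
#' @export
secondary_structure <- function(partner, sequence, energy = NULL,
                                params = fold_params(), validate = TRUE) {
  sequence <- normalize_rna(sequence)
  partner <- as.integer(partner)
  n <- nchar(sequence)
  if (length(partner) != n) stop("partner vector length != sequence length", call. = FALSE)
  if (validate) validate_structure(partner, sequence, params)
  if (is.null(energy)) energy <- structure_energy(partner, sequence, params)
  structure(list(partner = partner, energy = energy), class = "secondary_structure")
}

# score = sum of pair scores over the pairs of the structure
structure_energy <- function(partner, sequence, params = fold_params()) {
  i <- which(partner > seq_along(partner))
  if (length(i) == 0L) return(0)
  b <- seq_chars(normalize_rna(sequence))
  S <- pair_score_matrix(b, params)
  sum(S[cbind(i, partner[i])])
}

validate_structure <- function(partner, sequence, params = fold_params()) {
  n <- length(partner)
  paired <- which(partner != 0L)
  if (any(partner < 0L | partner > n)) stop("partner index out of range", call. = FALSE)
  if (any(partner[paired] == paired)) stop("position paired with itself", call. = FALSE)
  if (!all(partner[partner[paired]] == paired)) {
    stop("pairing is not an involution", call. = FALSE)
  }
  op <- which(partner > seq_len(n))
  if (any(partner[op] - op - 1L < params$min_loop)) {
    stop("hairpin loop shorter than the minimum of ", params$min_loop, call. = FALSE)
  }
  b <- seq_chars(normalize_rna(sequence))
  S <- pair_score_matrix(b, params)
  if (any(is.na(S[cbind(op, partner[op])]))) {
    stop("disallowed base pair (only AU, GC and GU wobble pairs are legal)",
         call. = FALSE)
  }
  # nestedness: opening/closing must balance like brackets
  depth <- 0L
  for (i in seq_len(n)) {
    if (partner[i] > i) depth <- depth + 1L
    else if (partner[i] != 0L && partner[i] < i) depth <- depth - 1L
  }
  if (length(op) >= 2L) {
    cl <- partner[op]
    for (a in seq_along(op)) {
      crossing <- op > op[a] & op <= cl[a] & cl > cl[a]
      if (any(crossing)) stop("crossing base pairs (pseudoknot) are not allowed",
                              call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Minimum-energy DP over nested structures.  Returns an (n+1) x (n+1)
# matrix E1 where E1[i, j + 1] is the optimum for the closed interval
# [i, j] (j + 1 offset so the empty interval j = i - 1 is addressable).
fold_dp_matrix <- function(S, min_loop) {
  n <- nrow(S)
  E <- matrix(0, n + 1L, n + 1L)
  if (n == 0L) return(E)
  for (span in seq_len(n)) {
    for (i in seq_len(n - span + 1L)) {
      j <- i + span - 1L
      best <- E[i + 1L, j + 1L]  # i unpaired
      if (span >= min_loop + 2L) {
        ks <- (i + min_loop + 1L):j
        sc <- S[i, ks]
        ok <- !is.na(sc)
        if (any(ok)) {
          ks <- ks[ok]
          cand <- sc[ok] + E[i + 1L, ks - 1L + 1L] + E[cbind(ks + 1L, j + 1L)]
          best <- min(best, cand)
        }
      }
      E[i, j + 1L] <- best
    }
  }
  E
}

# Enumerate every nested structure of [i, j] with energy <= maxE.
# Returns a list of list(pairs = 2-column matrix, e = energy).
enumerate_band <- function(i, j, maxE, S, E, min_loop) {
  if (i > j) return(list(list(pairs = NULL, e = 0)))
  out <- list()
  # option 1: i unpaired
  if (E[i + 1L, j + 1L] <= maxE + 1e-9) {
    out <- enumerate_band(i + 1L, j, maxE, S, E, min_loop)
  }
  # option 2: i paired with k
  if (j - i >= min_loop + 1L) {
    for (k in (i + min_loop + 1L):j) {
      ps <- S[i, k]
      if (is.na(ps)) next
      lb <- ps + E[i + 1L, k - 1L + 1L] + E[k + 1L, j + 1L]
      if (lb > maxE + 1e-9) next
      left <- enumerate_band(i + 1L, k - 1L, maxE - ps - E[k + 1L, j + 1L],
                             S, E, min_loop)
      for (s1 in left) {
        rem <- maxE - ps - s1$e
        right <- enumerate_band(k + 1L, j, rem, S, E, min_loop)
        for (s2 in right) {
          out[[length(out) + 1L]] <- list(
            pairs = rbind(s1$pairs, s2$pairs, c(i, k)),
            e = ps + s1$e + s2$e
          )
        }
      }
    }
  }
  out
}

# log partition function matrix at temperature kT (same offset as E)
fold_logZ_matrix <- function(S, min_loop, kT) {
  n <- nrow(S)
  Z <- matrix(0, n + 1L, n + 1L)
  if (n == 0L) return(Z)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  for (span in seq_len(n)) {
    for (i in seq_len(n - span + 1L)) {
      j <- i + span - 1L
      terms <- Z[i + 1L, j + 1L]
      if (span >= min_loop + 2L) {
        ks <- (i + min_loop + 1L):j
        sc <- S[i, ks]
        ok <- !is.na(sc)
        if (any(ok)) {
          ks <- ks[ok]
          terms <- c(terms,
                     -sc[ok] / kT + Z[i + 1L, ks - 1L + 1L] + Z[cbind(ks + 1L, j + 1L)])
        }
      }
      Z[i, j + 1L] <- lse(terms)
    }
  }
  Z
}

# one stochastic traceback through the partition function
sample_traceback <- function(S, Z, min_loop, kT, n) {
  partner <- integer(n)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    if (i > j) next
    lw <- Z[i + 1L, j + 1L]
    ks <- integer(0)
    if (j - i >= min_loop + 1L) {
      kk <- (i + min_loop + 1L):j
      sc <- S[i, kk]
      ok <- !is.na(sc)
      if (any(ok)) {
        ks <- kk[ok]
        lw <- c(lw, -sc[ok] / kT + Z[i + 1L, ks - 1L + 1L] + Z[cbind(ks + 1L, j + 1L)])
      }
    }
    m <- max(lw)
    w <- exp(lw - m)
    pick <- sample.int(length(w), 1L, prob = w)
    if (pick == 1L) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
    } else {
      k <- ks[pick - 1L]
      partner[i] <- k
      partner[k] <- i
      stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
      stack[[length(stack) + 1L]] <- c(k + 1L, j)
    }
  }
  partner
}

# deterministic minimum-energy traceback
mfe_traceback <- function(S, E, min_loop, n) {
  partner <- integer(n)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    if (i > j) next
    e <- E[i, j + 1L]
    if (abs(E[i + 1L, j + 1L] - e) < 1e-9) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
      next
    }
    done <- FALSE
    for (k in (i + min_loop + 1L):j) {
      ps <- S[i, k]
      if (is.na(ps)) next
      if (abs(ps + E[i + 1L, k - 1L + 1L] + E[k + 1L, j + 1L] - e) < 1e-9) {
        partner[i] <- k; partner[k] <- i
        stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        stack[[length(stack) + 1L]] <- c(k + 1L, j)
        done <- TRUE
        break
      }
    }
    if (!done) stop("internal error: minimum-energy traceback failed")
  }
  partner
}

#' Fold a sequence into a secondary-structure ensemble
#'
#' For sequences up to `params$exhaustive_cutoff` nucleotides the ensemble
#' is exhaustive: every valid nested structure within `params$epsilon`
#' score units of the optimum, deterministically ordered by (energy, then
#' lexicographic pairing). Longer sequences are sampled: `params$n_samples`
#' Boltzmann-weighted draws from the nested-structure partition function
#' at temperature `params$kT`, seeded by `params$seed`, with the optimum
#' prepended if it was not drawn.
#'
#' @param sequence Nucleotide string (A/C/G/U or T).
#' @param params A [fold_params()] object.
#' @return Object of class `structure_ensemble`: fields `sequence`,
#'   `structures` (list of `secondary_structure`), `n_structures`,
#'   `source` (`"computed"`), `mode` (`"exhaustive"`/`"sampled"`), `seed`
#'   and `params`.
#' @examples
#' fold_ensemble("GGGAAAACCC")
#' @export
fold_ensemble <- function(sequence, params = fold_params()) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("sequence must be non-empty", call. = FALSE)
  b <- seq_chars(sequence)
  S <- pair_score_matrix(b, params)
  E <- fold_dp_matrix(S, params$min_loop)

  to_struct <- function(pairs, e) {
    partner <- integer(n)
    if (!is.null(pairs)) {
      partner[pairs[, 1]] <- pairs[, 2]
      partner[pairs[, 2]] <- pairs[, 1]
    }
    structure(list(partner = partner, energy = e), class = "secondary_structure")
  }

  if (n <= params$exhaustive_cutoff) {
    raw <- enumerate_band(1L, n, E[1L, n + 1L] + params$epsilon, S, E,
                          params$min_loop)
    structs <- lapply(raw, function(s) to_struct(s$pairs, s$e))
    key <- vapply(structs, function(s) paste(s$partner, collapse = ","), character(1))
    ord <- order(vapply(structs, `[[`, numeric(1), "energy"), key)
    structs <- structs[ord]
    mode <- "exhaustive"
    seed <- NA_integer_
  } else {
    Z <- fold_logZ_matrix(S, params$min_loop, params$kT)
    seed <- params$seed
    samples <- local({
      if (!is.null(seed) && !is.na(seed)) set.seed(seed)
      lapply(seq_len(params$n_samples), function(.)
        sample_traceback(S, Z, params$min_loop, params$kT, n))
    })
    mfe <- mfe_traceback(S, E, params$min_loop, n)
    if (!any(vapply(samples, identical, logical(1), mfe))) {
      samples <- c(list(mfe), samples[-length(samples)])
    }
    structs <- lapply(samples, function(p) {
      i <- which(p > seq_len(n))
      e <- if (length(i)) sum(S[cbind(i, p[i])]) else 0
      structure(list(partner = p, energy = e), class = "secondary_structure")
    })
    mode <- "sampled"
  }

  structure(list(sequence = sequence, structures = structs,
                 n_structures = length(structs), source = "computed",
                 mode = mode, seed = seed, params = params),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("structure_ensemble: %d nt, %d structures (%s, %s)\n",
              nchar(x$sequence), x$n_structures, x$mode %||% "imported", x$source))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a dot-bracket string into a partner vector
#'
#' @param db Dot-bracket string over `.`, `(` and `)`.
#' @return Integer partner vector (0 = unpaired).
#' @export
parse_dotbracket <- function(db) {
  ch <- seq_chars(gsub("[[:space:]]", "", db))
  if (any(!ch %in% c(".", "(", ")"))) {
    stop("dot-bracket string may contain only '.', '(' and ')'", call. = FALSE)
  }
  partner <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) {
        stop("unbalanced ')' at position ", i, call. = FALSE)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack) > 0L) {
    stop("unbalanced '(' at position ", stack[length(stack)], call. = FALSE)
  }
  partner
}

#' Serialize a partner vector as dot-bracket
#' @param partner Integer partner vector (0 = unpaired).
#' @return Dot-bracket string.
#' @export
format_dotbracket <- function(partner) {
  ch <- rep(".", length(partner))
  ch[partner > seq_along(partner)] <- "("
  ch[partner != 0L & partner < seq_along(partner)] <- ")"
  paste(ch, collapse = "")
}

#' Read a CT (connect) file
#'
#' mfold/UNAFold dialect: a header line carrying the length (and usually
#' an energy after `=`), then one line per position with columns
#' index, base, previous, next, partner, index.
#'
#' @param path CT file.
#' @return List with `sequence`, `partner` and `energy` (NA if absent).
#' @export
read_ct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("CT file too short: ", path, call. = FALSE)
  hdr <- trimws(lines[1])
  n <- suppressWarnings(as.integer(strsplit(hdr, "\\s+")[[1]][1]))
  if (is.na(n)) stop("CT header does not start with the sequence length", call. = FALSE)
  energy <- suppressWarnings(
    as.numeric(sub(".*=\\s*(-?[0-9.]+).*", "\\1", hdr)))
  if (identical(sub(".*=\\s*(-?[0-9.]+).*", "\\1", hdr), hdr)) energy <- NA_real_
  if (length(lines) - 1L < n) {
    stop("CT file declares ", n, " positions but has ", length(lines) - 1L,
         " records", call. = FALSE)
  }
  base <- character(n)
  partner <- integer(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(f) < 5L || is.na(suppressWarnings(as.integer(f[1])))) {
      stop("malformed CT line ", i + 1L, " in ", path, call. = FALSE)
    }
    if (as.integer(f[1]) != i) {
      stop("CT line ", i + 1L, ": index ", f[1], " where ", i, " expected",
           call. = FALSE)
    }
    base[i] <- f[2]
    partner[i] <- as.integer(f[5])
  }
  paired <- which(partner != 0L)
  bad <- paired[partner[partner[paired]] != paired]
  if (length(bad) > 0L) {
    stop("CT pairing inconsistent at position ", bad[1],
         " (i says j but j does not say i)", call. = FALSE)
  }
  list(sequence = paste(base, collapse = ""), partner = partner, energy = energy)
}

#' Import an externally computed structure ensemble
#'
#' Accepts a mix of CT files and dot-bracket files (a dot-bracket file may
#' hold a `>` header, an optional sequence line, and one structure line
#' per record). All files must describe `sequence` (case- and
#' T/U-insensitive).
#'
#' @param files Character vector of file paths.
#' @param sequence The sequence the structures belong to.
#' @param params [fold_params()] used to score structures lacking an
#'   energy and to validate them.
#' @return A `structure_ensemble` with `source == "imported"`.
#' @export
import_ensemble <- function(files, sequence, params = fold_params()) {
  sequence <- normalize_rna(sequence)
  if (length(files) == 0L) stop("no structure files given", call. = FALSE)
  check_seq <- function(s, origin) {
    s <- normalize_rna(s)
    if (nchar(s) != nchar(sequence)) {
      stop(origin, ": sequence length ", nchar(s), " != expected ",
           nchar(sequence), call. = FALSE)
    }
    a <- seq_chars(s); b <- seq_chars(sequence)
    d <- which(a != b)
    if (length(d) > 0L) {
      stop(origin, ": sequence differs from the given one first at position ",
           d[1], " ('", a[d[1]], "' vs '", b[d[1]], "')", call. = FALSE)
    }
  }
  structs <- list()
  for (f in files) {
    lines <- readLines(f, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    first <- trimws(lines[1])
    if (grepl("^[0-9]+(\\s|$)", first)) {
      ct <- read_ct(f)
      check_seq(ct$sequence, f)
      structs[[length(structs) + 1L]] <-
        secondary_structure(ct$partner, sequence,
                            energy = if (is.na(ct$energy)) NULL else ct$energy,
                            params = params)
    } else {
      for (ln in lines) {
        ln <- trimws(ln)
        if (startsWith(ln, ">")) next
        core <- sub("\\s*\\(-?[0-9.]+\\)\\s*$", "", ln)  # trailing energy
        if (grepl("^[.()]+$", core)) {
          partner <- parse_dotbracket(core)
          if (length(partner) != nchar(sequence)) {
            stop(f, ": dot-bracket length ", length(partner),
                 " != sequence length ", nchar(sequence), call. = FALSE)
          }
          structs[[length(structs) + 1L]] <-
            secondary_structure(partner, sequence, params = params)
        } else if (grepl("^[ACGUTacgut]+$", core)) {
          check_seq(core, f)
        } else {
          stop(f, ": unrecognized line '", substr(ln, 1, 40), "'", call. = FALSE)
        }
      }
    }
  }
  if (length(structs) == 0L) stop("no structures found in the given files",
                                  call. = FALSE)
  structure(list(sequence = sequence, structures = structs,
                 n_structures = length(structs), source = "imported",
                 mode = "imported", seed = NA_integer_, params = params),
            class = "structure_ensemble")
}
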