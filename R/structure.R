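#' Find maximal tandem runs of a motif
#'
#' Scans a sequence for every maximal tandem run `motif^count` (count >= 1).
#' A run is maximal when it cannot be extended by another full motif copy on
#' either side; maximal runs at different phase offsets may overlap and are
#' all reported.
#'
#' @param seq Nucleotide string.
#' @param motif Repeat-unit string.
#' @return A data frame with columns `start` (1-based) and `count`, ordered
#'   by start.
#' @export
find_motif_runs <- function(seq, motif) {
  m <- .motif_runs(seq, motif)
  data.frame(start = m[, 1L], count = m[, 2L])
}

# matrix version used internally: columns start, count
.motif_runs <- function(seq, motif) {
  k <- nchar(motif)
  n <- nchar(seq)
  stopifnot(k >= 1L)
  if (n < k) return(matrix(integer(0), ncol = 2L))
  pos <- seq_len(n - k + 1L)
  starts <- pos[substring(seq, pos, pos + k - 1L) == motif]
  if (!length(starts)) return(matrix(integer(0), ncol = 2L))
  hit <- logical(n)
  hit[starts] <- TRUE
  out <- integer(0)
  for (s in starts) {
    if (s - k >= 1L && hit[s - k]) next  # interior of a longer chain
    cnt <- 1L
    while (s + cnt * k <= n - k + 1L && hit[s + cnt * k]) cnt <- cnt + 1L
    out <- c(out, s, cnt)
  }
  matrix(out, ncol = 2L, byrow = TRUE)
}

# ---- internal decomposition representation -------------------------------
# a decomposition of an interval is summarised as
#   list(cost, runs)  with runs an integer matrix (start, len, motif index)
# cost counts interrupt bases + interrupt segments inside the interval only.

.empty_runs <- matrix(integer(0), ncol = 3L)

# blocks (kind/seq/count vectors) for a full-sequence decomposition
.runs_to_blocks <- function(seq, motifs, runs) {
  n <- nchar(seq)
  kind <- character(0); bseq <- character(0); bcount <- integer(0)
  ord <- order(runs[, 1L])
  pos <- 1L
  for (i in ord) {
    s <- runs[i, 1L]; len <- runs[i, 2L]
    if (s > pos) {
      kind <- c(kind, "INTERRUPT")
      bseq <- c(bseq, substr(seq, pos, s - 1L))
      bcount <- c(bcount, 1L)
    }
    motif <- motifs[runs[i, 3L]]
    kind <- c(kind, "MOTIF_RUN")
    bseq <- c(bseq, motif)
    bcount <- c(bcount, len %/% nchar(motif))
    pos <- s + len
  }
  if (pos <= n) {
    kind <- c(kind, "INTERRUPT")
    bseq <- c(bseq, substr(seq, pos, n))
    bcount <- c(bcount, 1L)
  }
  list(kind = kind, seq = bseq, count = bcount)
}

.blocks_bracket <- function(b) {
  paste(ifelse(b$kind == "INTERRUPT", b$seq,
               sprintf("[%s]%d", b$seq, b$count)),
        collapse = "_")
}

.build_structure <- function(seq, motifs, runs) {
  b <- .runs_to_blocks(seq, motifs, runs)
  is_int <- b$kind == "INTERRUPT"
  blocks <- data.frame(kind = b$kind, seq = b$seq, count = b$count,
                       stringsAsFactors = FALSE)
  structure(
    list(blocks = blocks,
         nonmotif_bases = sum(nchar(b$seq[is_int])),
         nonmotif_parts = sum(is_int),
         score = sum(nchar(b$seq[is_int])) + sum(is_int),
         core_len = nchar(seq),
         bracket = .blocks_bracket(b)),
    class = "repeat_structure"
  )
}

#' @export
print.repeat_structure <- function(x, ...) {
  cat(sprintf("<repeat_structure> %s  (len %d, score %d: %d non-motif bases in %d parts)\n",
              x$bracket, x$core_len, x$score, x$nonmotif_bases, x$nonmotif_parts))
  invisible(x)
}

#' Infer the repeat structure of an allele sequence
#'
#' Recursive branch-and-score decomposition of a candidate allele sequence
#' into tandem motif runs and literal interrupts. Every maximal run of every
#' motif found in a still-undecomposed region spawns a branch; the regions
#' left and right of the placed run are decomposed recursively and
#' independently (intervals are memoised, so equivalent branches are
#' explored once). A branch terminates when its remaining regions contain
#' no motif occurrence; those regions become literal interrupts. Recursion
#' depth is capped at `max_iterations` as a hard stop. Among terminal
#' decompositions the one minimising
#' `score = non-motif bases + non-motif parts` is returned (each contiguous
#' interrupt segment is one part). Ties are broken deterministically: fewer
#' blocks, then a longer leftmost motif run, then the lexicographically
#' smaller bracket string.
#'
#' @param seq Nucleotide string (a trimmed allele core, possibly padded).
#' @param motifs Character vector of repeat-unit strings of equal length.
#' @param max_iterations Recursion-depth cap (default 50).
#' @return An object of class `repeat_structure` with fields `blocks`
#'   (data frame `kind`/`seq`/`count`), `nonmotif_bases`, `nonmotif_parts`,
#'   `score`, `core_len` and `bracket` (e.g. `"[AAAG]16_AGAG_[GAAA]3"`).
#' @export
infer_structure <- function(seq, motifs, max_iterations = 50L) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq),
            length(motifs) >= 1L)
  seq <- toupper(seq)
  motifs <- toupper(motifs)
  period <- nchar(motifs[1])
  if (any(nchar(motifs) != period))
    stop("motifs must have uniform length", call. = FALSE)
  n <- nchar(seq)
  if (n < period)
    return(.build_structure(seq, motifs, .empty_runs))

  memo <- new.env(hash = TRUE, parent = emptyenv())

  solve <- function(i, j, depth) {
    if (j < i) return(list(cost = 0L, runs = .empty_runs))
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cands <- .empty_runs
    if (depth < max_iterations) {
      gseq <- substr(seq, i, j)
      for (m in seq_along(motifs)) {
        mr <- .motif_runs(gseq, motifs[m])
        if (nrow(mr))
          cands <- rbind(cands, cbind(i + mr[, 1L] - 1L,
                                      mr[, 2L] * period, m))
      }
    }
    if (!nrow(cands)) {
      res <- list(cost = j - i + 2L,  # segment bases + one part
                  runs = .empty_runs)
      memo[[key]] <- res
      return(res)
    }
    best <- NULL
    best_aux <- NULL
    for (r in seq_len(nrow(cands))) {
      s <- cands[r, 1L]; e <- s + cands[r, 2L] - 1L
      left <- solve(i, s - 1L, depth + 1L)
      right <- solve(e + 1L, j, depth + 1L)
      cand <- list(cost = left$cost + right$cost,
                   runs = rbind(left$runs, cands[r, , drop = FALSE],
                                right$runs))
      if (is.null(best) || cand$cost < best$cost) {
        best <- cand; best_aux <- NULL
      } else if (cand$cost == best$cost) {
        if (is.null(best_aux)) best_aux <- .tiebreak_key(seq, motifs, best$runs)
        cand_aux <- .tiebreak_key(seq, motifs, cand$runs)
        if (.aux_better(cand_aux, best_aux)) {
          best <- cand; best_aux <- cand_aux
        }
      }
    }
    memo[[key]] <- best
    best
  }

  res <- solve(1L, n, 0L)
  .build_structure(seq, motifs, res$runs)
}

# tie-break key for equal-score decompositions: fewer blocks, longer
# leftmost motif run, lexicographically smaller bracket
.tiebreak_key <- function(seq, motifs, runs) {
  b <- .runs_to_blocks(seq, motifs, runs)
  i <- which(b$kind == "MOTIF_RUN")
  first_run <- if (!length(i)) 0L else b$count[i[1]] * nchar(b$seq[i[1]])
  list(nblocks = length(b$kind), first_run = first_run,
       bracket = .blocks_bracket(b))
}

.aux_better <- function(a, b) {
  if (a$nblocks != b$nblocks) return(a$nblocks < b$nblocks)
  if (a$first_run != b$first_run) return(a$first_run > b$first_run)
  a$bracket < b$bracket
}

#' Expand a bracket structure string back into a sequence
#'
#' Inverse of the bracket notation: tokens joined by `"_"`, motif runs as
#' `[MOTIF]count`, interrupts as literal sequence.
#'
#' @param bracket Bracket string, e.g. `"[AAAG]3_GA"`.
#' @return The expanded nucleotide string.
#' @export
expand_structure <- function(bracket) {
  stopifnot(is.character(bracket), length(bracket) == 1L, nzchar(bracket))
  tokens <- strsplit(bracket, "_", fixed = TRUE)[[1]]
  parts <- vapply(tokens, function(tok) {
    m <- regmatches(tok, regexec("^\\[([ACGTN]+)\\]([0-9]+)$", tok))[[1]]
    if (length(m) == 3L) {
      strrep(m[2], as.integer(m[3]))
    } else if (grepl("^[ACGTN]+$", tok)) {
      tok
    } else {
      stop("malformed bracket token: '", tok, "'", call. = FALSE)
    }
  }, "", USE.NAMES = FALSE)
  paste(parts, collapse = "")
}

#' Derive the CE-compatible allele designation
#'
#' The designation is length-based: with `L` the structure's core length
#' minus the retained pads plus the locus designation offset, the allele is
#' `n = floor(L / period)` full repeat units, written `"n"` when `L` is an
#' exact multiple of the period and `"n.r"` with `r = L mod period`
#' otherwise (e.g. a 98-nt FGA core gives `"24.2"`). Length-based counting
#' deliberately includes non-motif stretches interior to the repeat region,
#' matching forensic nomenclature for variant alleles; `designation_offset`
#' carries any locus-specific correction.
#'
#' @param structure A `repeat_structure` (or any object with `core_len`),
#'   or a bare core length.
#' @param locus A [panel_locus()] supplying `period` and
#'   `designation_offset`.
#' @param pads Integer vector of length 2: retained flank bases on each
#'   side of the core (default `c(3, 3)`).
#' @return The designation string.
#' @export
designate_allele <- function(structure, locus, pads = c(3L, 3L)) {
  core_len <- if (is.numeric(structure)) structure else structure$core_len
  L <- core_len - sum(pads) + locus$designation_offset
  if (L <= 0)
    stop("invalid allele: non-positive repeat length at locus '",
         locus$name, "'", call. = FALSE)
  n <- L %/% locus$period
  r <- L %% locus$period
  if (r == 0) as.character(n) else paste0(n, ".", r)
}
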