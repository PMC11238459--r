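# Branch evolution of exon (codon-level) and intron (nucleotide-level)
# sequences. Every mutation is recorded in a log whose sequential replay on
# the ancestral sequence reproduces the descendant sequence exactly; the
# alignment module threads the same logs through the global column system.
#
# Log entries are lists with fields:
#   kind = "substitution": pos (1-based, current coords), old, new (1 nt)
#   kind = "insertion":    pos (0-based, insert after pos), seq
#   kind = "deletion":     pos (1-based start), len, seq (deleted segment)

# HKY-weighted replacement kernel: transitions (A<->G, C<->T) get weight
# kappa, transversions weight 1; equal base frequencies (composition is
# handled by the generating Markov chains).
substituteBase <- function(base, kappa, exclude = character(0)) {
  cand <- setdiff(NT, c(base, exclude))
  if (!length(cand)) return(NA_character_)
  ts <- c(A = "G", G = "A", C = "T", T = "C")[base]
  w <- ifelse(cand == ts, kappa, 1)
  cand[sample.int(length(cand), 1L, prob = w)]
}

truncGeomDraw <- function(meanLen, cap) {
  # truncated geometric on 1..cap with the given untruncated mean
  p <- 1 / max(meanLen, 1)
  min(stats::rgeom(1L, p) + 1L, cap)
}

codonAt <- function(chars, i) paste(chars[i:(i + 2L)], collapse = "")

#' Evolve an exon sequence along a branch
#'
#' Applies codon-level evolution: single-nucleotide substitutions whose
#' count is Poisson with mean `exSubRate * branchLength * length(seq)`,
#' and whole-codon insertions/deletions (counts each Poisson with mean
#' `exIndelRate / 2 * branchLength * length(seq)`; lengths are truncated
#' geometric in codons). Substitutions that would create a frame-0 stop
#' codon are resampled among the non-stop alternatives, so the realized
#' substitution count equals the Poisson draw. Deletions never remove the
#' last remaining codon. The output length stays a multiple of 3.
#'
#' @param seq DNA string, length a multiple of 3.
#' @param branchLength branch length (expected substitutions per site).
#' @param config a [SpliceSimConfig-class].
#' @return `list(seq = <descendant DNA>, log = <list of events>)`;
#'   [replaySequenceLog()] on the input reproduces `seq` exactly.
#' @export
evolveExonSequence <- function(seq, branchLength, config) {
  if (nchar(seq) %% 3 != 0) stop("exon length must be a multiple of 3")
  sq <- config@sequence
  chars <- strsplit(seq, "")[[1]]
  log <- list()
  if (branchLength > 0) {
    L <- length(chars)
    nSub <- stats::rpois(1L, sq$exSubRate * branchLength * L)
    for (i in seq_len(nSub)) {
      pos <- sample.int(length(chars), 1L)
      old <- chars[pos]
      cStart <- pos - (pos - 1L) %% 3L
      excl <- character(0)
      repeat {
        new <- substituteBase(old, sq$kappa, exclude = excl)
        if (is.na(new)) { new <- old; break }
        trial <- chars
        trial[pos] <- new
        if (!(codonAt(trial, cStart) %in% STOP_CODONS)) break
        excl <- c(excl, new)
      }
      if (new == old) next
      chars[pos] <- new
      log[[length(log) + 1L]] <- list(kind = "substitution", pos = pos,
                                      old = old, new = new)
    }
    lam <- sq$exIndelRate / 2 * branchLength * L
    nIns <- stats::rpois(1L, lam)
    nDel <- stats::rpois(1L, lam)
    ops <- sample(rep(c("ins", "del"), c(nIns, nDel)))
    for (op in ops) {
      nCod <- length(chars) %/% 3L
      if (op == "ins") {
        k <- truncGeomDraw(sq$exIndelMeanCodons, sq$maxIndelCodons)
        ins <- generateExonSequence(3L * k, sq$exonChain)
        at <- (sample.int(nCod + 1L, 1L) - 1L) * 3L
        chars <- append(chars, strsplit(ins, "")[[1]], after = at)
        log[[length(log) + 1L]] <- list(kind = "insertion", pos = at, seq = ins)
      } else {
        if (nCod <= 1L) next
        k <- min(truncGeomDraw(sq$exIndelMeanCodons, sq$maxIndelCodons),
                 nCod - 1L)
        startCod <- sample.int(nCod - k + 1L, 1L)
        from <- (startCod - 1L) * 3L + 1L
        len <- 3L * k
        gone <- paste(chars[from:(from + len - 1L)], collapse = "")
        chars <- chars[-(from:(from + len - 1L))]
        log[[length(log) + 1L]] <- list(kind = "deletion", pos = from,
                                        len = len, seq = gone)
      }
    }
  }
  list(seq = paste(chars, collapse = ""), log = log)
}

#' Evolve an intron sequence along a branch
#'
#' Nucleotide-level substitutions and arbitrary-length indels confined to
#' the interior of the intron; the terminal `GT`/`AG` dinucleotides are
#' never touched. Counts are Poisson in the interior length scaled by the
#' branch length; indel lengths are truncated geometric in nucleotides.
#'
#' @inheritParams evolveExonSequence
#' @param seq DNA string beginning `GT` and ending `AG`.
#' @return `list(seq =, log =)` as for [evolveExonSequence()].
#' @export
evolveIntronSequence <- function(seq, branchLength, config) {
  if (substr(seq, 1, 2) != "GT" || substring(seq, nchar(seq) - 1) != "AG")
    stop("intron must begin GT and end AG")
  sq <- config@sequence
  chars <- strsplit(seq, "")[[1]]
  log <- list()
  interior <- function() length(chars) - 4L
  if (branchLength > 0 && interior() > 0L) {
    nSub <- stats::rpois(1L, sq$inSubRate * branchLength * interior())
    for (i in seq_len(nSub)) {
      if (interior() < 1L) break
      pos <- 2L + sample.int(interior(), 1L)
      old <- chars[pos]
      new <- substituteBase(old, sq$kappa)
      chars[pos] <- new
      log[[length(log) + 1L]] <- list(kind = "substitution", pos = pos,
                                      old = old, new = new)
    }
    lam <- sq$inIndelRate / 2 * branchLength * interior()
    ops <- sample(rep(c("ins", "del"), c(stats::rpois(1L, lam),
                                         stats::rpois(1L, lam))))
    for (op in ops) {
      if (op == "ins") {
        k <- truncGeomDraw(sq$inIndelMeanNt, sq$maxIndelNt)
        ctx <- "GT"
        ins <- character(k)
        for (j in seq_len(k)) {
          ins[j] <- sampleBase(sq$intronChain, ctx)
          ctx <- paste0(substring(ctx, 2), ins[j])
        }
        at <- 1L + sample.int(length(chars) - 3L, 1L)  # after pos in 2..len-2
        chars <- append(chars, ins, after = at)
        log[[length(log) + 1L]] <- list(kind = "insertion", pos = at,
                                        seq = paste(ins, collapse = ""))
      } else {
        if (interior() < 1L) next
        k <- min(truncGeomDraw(sq$inIndelMeanNt, sq$maxIndelNt), interior())
        from <- 2L + sample.int(interior() - k + 1L, 1L)
        gone <- paste(chars[from:(from + k - 1L)], collapse = "")
        chars <- chars[-(from:(from + k - 1L))]
        log[[length(log) + 1L]] <- list(kind = "deletion", pos = from,
                                        len = k, seq = gone)
      }
    }
  }
  list(seq = paste(chars, collapse = ""), log = log)
}

#' Replay a sequence event log
#'
#' Applies the ordered substitution/insertion/deletion events of a log to
#' an ancestral sequence; by construction the result equals the descendant
#' sequence returned alongside the log.
#'
#' @param seq ancestral DNA string.
#' @param log list of events as produced by [evolveExonSequence()] /
#'   [evolveIntronSequence()].
#' @return the descendant DNA string.
#' @export
replaySequenceLog <- function(seq, log) {
  chars <- strsplit(seq, "")[[1]]
  for (ev in log) {
    if (ev$kind == "substitution") {
      if (chars[ev$pos] != ev$old)
        stop("integrity error: substitution replay mismatch at pos ", ev$pos)
      chars[ev$pos] <- ev$new
    } else if (ev$kind == "insertion") {
      chars <- append(chars, strsplit(ev$seq, "")[[1]], after = ev$pos)
    } else if (ev$kind == "deletion") {
      got <- paste(chars[ev$pos:(ev$pos + ev$len - 1L)], collapse = "")
      if (got != ev$seq)
        stop("integrity error: deletion replay mismatch at pos ", ev$pos)
      chars <- chars[-(ev$pos:(ev$pos + ev$len - 1L))]
    } else stop("unknown event kind: ", ev$kind)
  }
  paste(chars, collapse = "")
}
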