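NT <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Markov-chain parameters for sequence generation
#'
#' Exon and intron nucleotide sequences are generated from order-`k`
#' Markov chains: the probability of the next base depends on the
#' preceding `k` bases (the context). Parameters are a `4^k x 4` matrix of
#' transition probabilities, one row per context, columns `A,C,G,T`, each
#' row summing to 1.
#'
#' @param probs numeric matrix with `4^order` rows (rownames = contexts in
#'   alphabetical order) and 4 columns named `A,C,G,T`.
#' @param order positive integer chain order.
#' @return an object of class `MarkovChainParams`.
#' @export
markovChainParams <- function(probs, order = 2L) {
  order <- as.integer(order)
  if (order < 1L) stop("order must be a positive integer")
  ctx <- allContexts(order)
  if (!is.matrix(probs) || nrow(probs) != length(ctx) || ncol(probs) != 4L)
    stop("probs must be a ", length(ctx), " x 4 matrix for order ", order)
  if (is.null(rownames(probs))) rownames(probs) <- ctx
  if (!identical(sort(rownames(probs)), ctx))
    stop("probs rownames must be all length-", order, " DNA contexts")
  probs <- probs[ctx, , drop = FALSE]
  colnames(probs) <- NT
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-9))
    stop("each context's probabilities must be >= 0 and sum to 1 (tol 1e-9)")
  obj <- structure(list(order = order, probs = probs),
                   class = "MarkovChainParams")
  obj$stationary <- computeStationary(obj)  # cached; chains are sampled often
  obj
}

allContexts <- function(order) {
  g <- do.call(expand.grid, rep(list(NT), order))
  sort(apply(g[, rev(seq_len(order)), drop = FALSE], 1, paste, collapse = ""))
}

#' @describeIn markovChainParams bundled default chains (order 2): the
#'   `"exon"` chain is mildly GC-shifted with weak first-order
#'   autocorrelation; the `"intron"` chain is AT-rich, as non-coding
#'   sequence typically is.
#' @param class `"exon"` or `"intron"`.
#' @export
defaultMarkovParams <- function(class = c("exon", "intron")) {
  class <- match.arg(class)
  base <- if (class == "exon") c(A = 0.26, C = 0.25, G = 0.27, T = 0.22)
          else c(A = 0.30, C = 0.18, G = 0.20, T = 0.32)
  ctx <- allContexts(2L)
  probs <- t(vapply(ctx, function(cx) {
    last <- substr(cx, 2, 2)
    w <- base * (1 + 0.15 * (NT == last))
    w / sum(w)
  }, numeric(4)))
  colnames(probs) <- NT
  markovChainParams(probs, 2L)
}

#' Stationary context distribution of a Markov chain
#'
#' The chain over contexts (states = the last `order` bases) has
#' transition matrix `P[xy, yz] = probs[xy, z]`; its stationary
#' distribution is the leading left eigenvector, computed by
#' eigen-analysis. For an order-2 chain this is the expected long-run
#' dinucleotide frequency of generated sequences.
#'
#' @param params a `MarkovChainParams`.
#' @return named numeric over contexts, summing to 1.
#' @export
stationaryDistribution <- function(params) {
  if (!is.null(params$stationary)) return(params$stationary)
  computeStationary(params)
}

computeStationary <- function(params) {
  ctx <- rownames(params$probs)
  n <- length(ctx)
  P <- matrix(0, n, n, dimnames = list(ctx, ctx))
  for (i in seq_len(n)) {
    suffix <- substring(ctx[i], 2)
    for (b in NT) {
      j <- match(paste0(suffix, b), ctx)
      P[i, j] <- P[i, j] + params$probs[i, b]
    }
  }
  ev <- eigen(t(P))
  k <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, k])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), ctx)
}

# sample one base given a context row of probabilities
sampleBase <- function(params, context) {
  p <- params$probs[context, ]
  NT[sample.int(4L, 1L, prob = p)]
}

# initial context drawn from the stationary distribution
sampleContext <- function(params) {
  pi0 <- params$stationary
  if (is.null(pi0)) pi0 <- computeStationary(params)
  names(pi0)[sample.int(length(pi0), 1L, prob = pi0)]
}

#' Generate an exon (coding) sequence
#'
#' Generates `lengthNt` nucleotides from the exon Markov chain. Frame-0
#' stop codons (TAA/TAG/TGA) are excluded: any codon generated as a stop
#' is redrawn (its third base is forced to the highest-probability
#' non-stop-forming base if redrawing fails), since exons are modeled as
#' pieces of a coding sequence.
#'
#' @param lengthNt sequence length; must be a positive multiple of 3.
#' @param params a `MarkovChainParams` (defaults to the bundled exon chain).
#' @return a DNA string of exactly `lengthNt` characters.
#' @export
generateExonSequence <- function(lengthNt, params = defaultMarkovParams("exon")) {
  if (lengthNt < 3 || lengthNt %% 3 != 0)
    stop("domain error: exon length must be a positive multiple of 3")
  out <- character(lengthNt)
  ctx <- sampleContext(params)
  pos <- 0L
  while (pos < lengthNt) {
    codon <- character(3)
    for (tries in seq_len(50L)) {
      c2 <- ctx
      for (j in 1:3) {
        codon[j] <- sampleBase(params, c2)
        c2 <- paste0(substring(c2, 2), codon[j])
      }
      if (!(paste(codon, collapse = "") %in% STOP_CODONS)) break
    }
    if (paste(codon, collapse = "") %in% STOP_CODONS) {
      third <- names(sort(params$probs[c2, ], decreasing = TRUE))
      for (b in third) {
        codon[3] <- b
        if (!(paste(codon, collapse = "") %in% STOP_CODONS)) break
      }
    }
    out[pos + 1:3] <- codon
    pos <- pos + 3L
    ctx <- paste(out[(pos - params$order + 1):pos], collapse = "")
  }
  paste(out, collapse = "")
}

#' Generate an intron sequence
#'
#' Generates a sequence that begins with the canonical donor dinucleotide
#' `GT` and ends with the acceptor `AG`; the interior is generated from
#' the intron Markov chain conditioned on the `GT` prefix.
#'
#' @param lengthNt total intron length; must be >= 4.
#' @param params a `MarkovChainParams` (defaults to the bundled intron chain).
#' @return a DNA string of exactly `lengthNt` characters.
#' @export
generateIntronSequence <- function(lengthNt,
                                   params = defaultMarkovParams("intron")) {
  if (lengthNt < 4) stop("domain error: intron length must be >= 4")
  nInt <- lengthNt - 4L
  if (nInt == 0L) return("GTAG")
  interior <- character(nInt)
  ctx <- "GT"
  for (i in seq_len(nInt)) {
    interior[i] <- sampleBase(params, ctx)
    ctx <- paste0(substring(ctx, 2), interior[i])
  }
  paste0("GT", paste(interior, collapse = ""), "AG")
}

#' Read / write Markov-chain parameter files
#'
#' Tab-separated dialect with a header line and columns
#' `context  A  C  G  T`; one row per context, probabilities summing to 1.
#'
#' @param path file path.
#' @return `readMarkovParams()` returns a `MarkovChainParams`.
#' @export
readMarkovParams <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("context", NT) %in% names(df)))
    stop("Markov parameter file needs columns: context A C G T")
  probs <- as.matrix(df[, NT])
  rownames(probs) <- df$context
  markovChainParams(probs, order = nchar(df$context[1]))
}

#' @rdname readMarkovParams
#' @param params a `MarkovChainParams` to serialize.
#' @export
writeMarkovParams <- function(params, path) {
  df <- data.frame(context = rownames(params$probs), params$probs,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
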