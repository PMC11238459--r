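#' Build a simulation configuration
#'
#' Assembles and validates every tunable constant of the simulator. The
#' transcript-event defaults follow the tool's standard settings
#' (`kTc = 5`, `tcRs = 1`, `tcEs = 0.25`, `tcMe = 0.15`, `tcA5 = 0.15`,
#' `tcA3 = 0.15`, `tcIr = 0.15`, `tcTl = 0.05`). Structure and sequence
#' constants are package defaults documented below; all are dimensionless
#' rates unless stated otherwise.
#'
#' @param kTc constant factor scaling transcript-event budgets on branches
#'   (the root applies proportions directly, without `kTc` or the branch
#'   length).
#' @param tcA5,tcA3,tcEs,tcMe,tcIr relative proportions of the five
#'   alternative-splicing event types (alternative 5'/3' splice site,
#'   exon skipping, mutually exclusive exons, intron retention).
#' @param tcTl,tcRs relative proportions of regulated transcript loss and
#'   of transcript gain by random selection from the isoform pool.
#' @param structure named list overriding structure-evolution constants:
#'   `kSt` (constant factor), `loss`, `gain`, `dup` (event proportions),
#'   `exonCountMean`, `exonCountSd` (root exon count, clamped to >= 1),
#'   `exonLenMeanCodons`, `exonLenSdCodons` (root exon length in codons,
#'   clamped to >= 3 codons), `intronLenMean`, `intronLenSd` (root intron
#'   length in nt, clamped to >= 12).
#' @param sequence named list overriding sequence constants: `exSubRate`,
#'   `exIndelRate` (per-nt Poisson rates per unit branch length for exons),
#'   `exIndelMeanCodons` (mean codon indel length, truncated geometric),
#'   `inSubRate`, `inIndelRate`, `inIndelMeanNt` (intron counterparts),
#'   `kappa` (transition/transversion weight of the substitution kernel),
#'   `maxIndelCodons`, `maxIndelNt` (truncation caps), `exonChain`,
#'   `intronChain` (Markov-chain parameter objects from
#'   [markovChainParams()]; `NULL` uses the bundled defaults).
#' @param seed integer RNG seed; every stochastic draw of a simulation
#'   flows from it.
#' @return a validated [SpliceSimConfig-class] object.
#' @examples
#' cfg <- spliceSimConfig(seed = 7, tcIr = 0.1)
#' cfg
#' @export
spliceSimConfig <- function(kTc = 5, tcA5 = 0.15, tcA3 = 0.15, tcEs = 0.25,
                            tcMe = 0.15, tcIr = 0.15, tcTl = 0.05, tcRs = 1,
                            structure = list(), sequence = list(),
                            seed = 1L) {
  stDef <- list(kSt = 1, loss = 0.1, gain = 0.1, dup = 0.05,
                exonCountMean = 6, exonCountSd = 2,
                exonLenMeanCodons = 57, exonLenSdCodons = 15,
                intronLenMean = 150, intronLenSd = 50)
  sqDef <- list(exSubRate = 1, exIndelRate = 0.02, exIndelMeanCodons = 1.5,
                inSubRate = 1, inIndelRate = 0.05, inIndelMeanNt = 3,
                kappa = 2, maxIndelCodons = 10, maxIndelNt = 30,
                exonChain = NULL, intronChain = NULL)
  badSt <- setdiff(names(structure), names(stDef))
  badSq <- setdiff(names(sequence), names(sqDef))
  if (length(badSt) || length(badSq))
    stop("unknown config keys: ", paste(c(badSt, badSq), collapse = ", "))
  stDef[names(structure)] <- structure
  sqDef[names(sequence)] <- sequence
  if (is.null(sqDef$exonChain)) sqDef$exonChain <- defaultMarkovParams("exon")
  if (is.null(sqDef$intronChain)) sqDef$intronChain <- defaultMarkovParams("intron")
  tc <- c(a5 = tcA5, a3 = tcA3, es = tcEs, me = tcMe, ir = tcIr,
          tl = tcTl, rs = tcRs)
  for (k in c("exSubRate", "exIndelRate", "exIndelMeanCodons", "inSubRate",
              "inIndelRate", "inIndelMeanNt", "kappa")) {
    v <- sqDef[[k]]
    if (!is.numeric(v) || !is.finite(v) || v < 0)
      stop("sequence constant '", k, "' must be >= 0")
  }
  new("SpliceSimConfig", kTc = kTc, tc = tc, structure = stDef,
      sequence = sqDef, seed = as.integer(seed))
}

#' Read a configuration file
#'
#' Reads a flat YAML (or `key: value`) file whose keys match the arguments
#' of [spliceSimConfig()]; structure/sequence constants are given as
#' `structure.kSt: 1` style dotted keys. Keys supplied in `...` (e.g. from
#' CLI flags) override file values.
#'
#' @param path path to the YAML configuration file.
#' @param ... overrides, as `spliceSimConfig()` arguments.
#' @return a [SpliceSimConfig-class].
#' @export
readSpliceSimConfig <- function(path, ...) {
  raw <- yaml::yaml.load_file(path)
  if (!is.list(raw)) stop("config file must be a mapping of key: value pairs")
  args <- list(structure = list(), sequence = list())
  for (k in names(raw)) {
    if (grepl("^structure\\.", k)) {
      args$structure[[sub("^structure\\.", "", k)]] <- raw[[k]]
    } else if (grepl("^sequence\\.", k)) {
      args$sequence[[sub("^sequence\\.", "", k)]] <- raw[[k]]
    } else args[[k]] <- raw[[k]]
  }
  over <- list(...)
  for (k in names(over)) args[[k]] <- over[[k]]
  do.call(spliceSimConfig, args)
}

setMethod("show", "SpliceSimConfig", function(object) {
  cat("SpliceSimConfig\n")
  cat(sprintf("  kTc = %g, seed = %d\n", object@kTc, object@seed))
  cat("  transcript-event proportions:\n   ",
      paste(sprintf("tc_%s=%g", names(object@tc), object@tc),
            collapse = " "), "\n")
  st <- object@structure
  cat(sprintf("  structure: kSt=%g loss=%g gain=%g dup=%g\n",
              st$kSt, st$loss, st$gain, st$dup))
  invisible(NULL)
})

# Deterministic per-node RNG stream: a child node's draws depend only on
# (seed, node label), not on traversal order.
nodeSeed <- function(seed, nodeLabel) {
  h <- sum(utf8ToInt(nodeLabel) * seq_along(utf8ToInt(nodeLabel)) * 131)
  as.integer((as.numeric(seed) * 48271 + h * 7919 + 12345) %% 2147483647)
}

withNodeSeed <- function(seed, nodeLabel, expr) {
  set.seed(nodeSeed(seed, nodeLabel))
  expr
}
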