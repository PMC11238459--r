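# Transcript-set evolution: the core model. A transcript is a record
#   id        "node#k" identifier
#   node      guide-tree node label
#   exons     ordered subset of the node structure's exon ids
#   off5/off3 named numeric (by exon id): signed 5'/3' boundary offsets in
#             nt, multiples of 3; positive = extension into the flanking
#             intron, negative = trim into the exon
#   retained  intron ids whose sequence is included (intron retention)
#   source    transcript id it derives from (NA for gains)
#   origin    one of rs, conserved, a5, a3, es, me, ir

AS_KINDS <- c("es", "me", "a5", "a3", "ir")

#' Construct a transcript record
#'
#' Mostly used internally; exported so that known scenarios (for instance
#' a hand-built set of isoforms over a hand-built structure) can be fed to
#' [propagateTranscripts()] or [orthologGroups()] directly.
#'
#' @param id transcript identifier, conventionally `"<node>#<k>"`.
#' @param node guide-tree node label.
#' @param exons ordered character vector of exon ids.
#' @param off5,off3 named numeric boundary offsets (multiples of 3).
#' @param retained character vector of retained intron ids.
#' @param source id of the transcript this one derives from, or `NA`.
#' @param origin event type that created it.
#' @return a transcript record (a named list).
#' @export
makeTranscript <- function(id, node, exons, off5 = NULL, off3 = NULL,
                           retained = character(0), source = NA_character_,
                           origin = "rs") {
  off5 <- if (is.null(off5)) stats::setNames(numeric(0), character(0)) else off5
  off3 <- if (is.null(off3)) stats::setNames(numeric(0), character(0)) else off3
  if (any(c(off5, off3) %% 3 != 0))
    stop("boundary offsets must be multiples of 3")
  list(id = id, node = node, exons = exons, off5 = off5, off3 = off3,
       retained = retained, source = source, origin = origin)
}

# canonical signature: two transcripts are "the same isoform" iff equal
txSignature <- function(tx) {
  o5 <- tx$off5[tx$off5 != 0]
  o3 <- tx$off3[tx$off3 != 0]
  off <- c(if (length(o5)) stats::setNames(o5, paste0(names(o5), "<")),
           if (length(o3)) stats::setNames(o3, paste0(names(o3), ">")))
  offStr <- if (length(off)) {
    ord <- sort(names(off))
    paste(paste0(ord, off[ord]), collapse = ",")
  } else ""
  paste(paste(tx$exons, collapse = "+"), offStr,
        paste(sort(tx$retained), collapse = ","), sep = "|")
}

#' Size of the isoform pool
#'
#' A gene structure with `m` exons admits `2^m - 1` non-empty exon
#' combinations.
#'
#' @param m exon count, >= 1.
#' @return `2^m - 1`.
#' @export
isoformPoolSize <- function(m) {
  if (m < 1) stop("domain error: m must be >= 1")
  2^m - 1
}

#' Draw the number of transcripts selected at the root
#'
#' The number of initial transcripts follows a normal distribution with
#' mean 1.45 and standard deviation 1.08 (the mean and sd of transcripts
#' per gene across the Eukaryote kingdom in Ensembl Compara). The raw draw
#' is rounded to the nearest integer and clamped to a minimum of 1.
#'
#' @param n number of draws.
#' @param raw if `TRUE`, return the raw normal draws before
#'   rounding/clamping.
#' @return integer vector (or numeric when `raw = TRUE`).
#' @export
sampleRootTranscriptCount <- function(n = 1L, raw = FALSE) {
  x <- stats::rnorm(n, mean = 1.45, sd = 1.08)
  if (raw) return(x)
  pmax(1L, as.integer(round(x)))
}

# Uniform sample of `n` distinct isoforms (exon subsets, no offsets) from
# the 2^m - 1 pool, excluding the given signatures. Enumerates for small m,
# rejection-samples otherwise. Returns a list of exon-id vectors; may
# return fewer than n when the pool is exhausted.
sampleIsoforms <- function(structure, n, excludeSignatures = character(0)) {
  m <- length(structure@exonIds)
  picked <- list()
  seen <- excludeSignatures
  sigOf <- isoformSignature
  if (m <= 12L) {
    masks <- seq_len(2^m - 1)
    subsets <- lapply(masks, function(b)
      structure@exonIds[bitwAnd(b, 2^(seq_len(m) - 1)) > 0])
    sigs <- vapply(subsets, sigOf, "")
    avail <- which(!(sigs %in% seen))
    if (length(avail)) {
      take <- sample(avail, min(n, length(avail)))
      picked <- subsets[take]
    }
  } else {
    tries <- 0L
    while (length(picked) < n && tries < 200L * n) {
      tries <- tries + 1L
      keep <- stats::runif(m) < 0.5
      if (!any(keep)) next
      exons <- structure@exonIds[keep]
      s <- sigOf(exons)
      if (s %in% seen) next
      seen <- c(seen, s)
      picked[[length(picked) + 1L]] <- exons
    }
  }
  picked
}

# signature of a zero-offset isoform, comparable with txSignature()
isoformSignature <- function(exons) {
  paste(paste(exons, collapse = "+"), "", "", sep = "|")
}

# condition signalled when a drawn (transcript, kind) cannot be applied
inapplicableEvent <- function(msg) {
  stop(structure(class = c("spliceforestInapplicable", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

perSideExtensionCap <- function(intronLen) {
  max(0L, (((intronLen - 6L) %/% 2L) %/% 3L) * 3L)
}

#' Apply one alternative-splicing event to a transcript
#'
#' Produces a new transcript derived from `tx` by one event of the given
#' kind. `es` removes one uniformly chosen exon (the result must stay
#' non-empty); `me` swaps one present exon for one structure exon absent
#' from the transcript; `a5`/`a3` shift the 5'/3' boundary of one
#' uniformly chosen exon by a nonzero multiple of 3 (sign uniform,
#' truncated-geometric magnitude, clamped so the exon core keeps >= 3 nt
#' and so that an extension never claims more than half the flanking
#' intron); `ir` retains one intron lying between two consecutive exons of
#' the transcript (its included length is trimmed to a multiple of 3 at
#' assembly time). When the kind cannot apply (es on a single-exon
#' transcript, me with no absent exon, ir with no eligible junction, a5/a3
#' with no movable boundary) an error of class `spliceforestInapplicable`
#' is signalled and the caller redraws.
#'
#' @param tx a transcript record.
#' @param kind one of `"es"`, `"me"`, `"a5"`, `"a3"`, `"ir"`.
#' @param structure the [GeneStructure-class] of the transcript's node.
#' @param newId identifier for the derived transcript.
#' @return a new transcript record with `source = tx$id`.
#' @export
applyASEvent <- function(tx, kind, structure, newId = paste0(tx$id, "*")) {
  kind <- match.arg(kind, AS_KINDS)
  exIds <- structure@exonIds
  sIdx <- match(tx$exons, exIds)
  if (any(is.na(sIdx))) stop("transcript references exons absent from structure")
  out <- tx
  out$id <- newId
  out$source <- tx$id
  out$origin <- kind
  if (kind == "es") {
    if (length(tx$exons) < 2L)
      inapplicableEvent("es needs a transcript with >= 2 exons")
    drop <- sample.int(length(tx$exons), 1L)
    gone <- tx$exons[drop]
    out$exons <- tx$exons[-drop]
    out$off5 <- out$off5[names(out$off5) != gone]
    out$off3 <- out$off3[names(out$off3) != gone]
  } else if (kind == "me") {
    absent <- setdiff(exIds, tx$exons)
    if (!length(absent)) inapplicableEvent("me needs an absent structure exon")
    gone <- tx$exons[sample.int(length(tx$exons), 1L)]
    add <- absent[sample.int(length(absent), 1L)]
    keep <- setdiff(tx$exons, gone)
    out$exons <- exIds[sort(match(c(keep, add), exIds))]
    out$off5 <- out$off5[names(out$off5) != gone]
    out$off3 <- out$off3[names(out$off3) != gone]
  } else if (kind %in% c("a5", "a3")) {
    ord <- sample.int(length(tx$exons))
    done <- FALSE
    for (pick in ord) {
      ex <- tx$exons[pick]
      k <- sIdx[pick]
      exonLen <- nchar(structure@exonSeqs[k])
      intron <- if (kind == "a5") {
        if (k > 1L) k - 1L else NA_integer_
      } else {
        if (k < length(exIds)) k else NA_integer_
      }
      hi <- if (is.na(intron)) 0L
            else perSideExtensionCap(nchar(structure@intronSeqs[intron]))
      cur5 <- if (ex %in% names(tx$off5)) tx$off5[[ex]] else 0
      cur3 <- if (ex %in% names(tx$off3)) tx$off3[[ex]] else 0
      cur <- if (kind == "a5") cur5 else cur3
      other <- if (kind == "a5") cur3 else cur5
      lo <- -max(0L, exonLen - 3L - max(0, -other))
      lo <- -(( -lo) %/% 3L) * 3L
      delta <- 3L * truncGeomDraw(1.5, 5L) * sample(c(-1L, 1L), 1L)
      for (d in c(delta, -delta)) {
        newOff <- min(max(cur + d, lo), hi)
        if (newOff != cur) {
          if (kind == "a5") out$off5[ex] <- newOff else out$off3[ex] <- newOff
          done <- TRUE
          break
        }
      }
      if (done) break
    }
    if (!done) inapplicableEvent(paste(kind, "has no movable boundary"))
  } else if (kind == "ir") {
    elig <- eligibleJunctions(tx, structure)
    if (!length(elig)) inapplicableEvent("ir needs an unretained junction")
    out$retained <- c(tx$retained,
                      elig[sample.int(length(elig), 1L)])
  }
  if (identical(txSignature(out), txSignature(tx)))
    inapplicableEvent("event did not change the transcript")
  out
}

# intron ids between structure-consecutive transcript exons, not yet retained
eligibleJunctions <- function(tx, structure) {
  sIdx <- match(tx$exons, structure@exonIds)
  out <- character(0)
  if (length(sIdx) > 1L) {
    for (j in seq_len(length(sIdx) - 1L)) {
      if (sIdx[j + 1L] == sIdx[j] + 1L) {
        iid <- structure@intronIds[sIdx[j]]
        if (!(iid %in% tx$retained)) out <- c(out, iid)
      }
    }
  }
  out
}

#' Run one evolutionary stage
#'
#' An evolutionary stage converts a set of source transcripts into a sink
#' set by applying `budget` events of one AS type: each event picks a
#' source uniformly at random, derives a new transcript from it, and links
#' the sink to that single source. Sinks do not become sources within the
#' same stage; the returned source set (`sources` plus the new sinks)
#' feeds the next stage. When a drawn source cannot undergo the event, the
#' source is redrawn up to `length(sources)` times; remaining budget that
#' cannot be honoured is reported as a shortfall.
#'
#' @param sources list of source transcript records.
#' @param kind the AS event type.
#' @param budget number of events to apply (see [eventBudget()]).
#' @param structure the [GeneStructure-class] the sinks live on.
#' @param nodeId node label used to mint sink ids.
#' @param counter an environment with an integer `k`, incremented per sink
#'   (minting `"<nodeId>#<k>"` ids); created fresh when omitted.
#' @return `list(sources = <sources + sinks>, sinks =, records =
#'   data.frame(source_id, sink_id), nApplied =, budget =)`.
#' @export
runEvolutionaryStage <- function(sources, kind, budget, structure, nodeId,
                                 counter = NULL) {
  if (is.null(counter)) {
    counter <- new.env(parent = emptyenv())
    counter$k <- length(sources)
  }
  sinks <- list()
  recs <- data.frame(source_id = character(0), sink_id = character(0),
                     stringsAsFactors = FALSE)
  nApplied <- 0L
  for (e in seq_len(budget)) {
    if (!length(sources)) break
    okTx <- NULL
    for (try in seq_len(max(1L, length(sources)))) {
      src <- sources[[sample.int(length(sources), 1L)]]
      counter$k <- counter$k + 1L
      cand <- tryCatch(
        applyASEvent(src, kind, structure,
                     newId = paste0(nodeId, "#", counter$k)),
        spliceforestInapplicable = function(e) NULL)
      if (!is.null(cand)) { okTx <- cand; break }
      counter$k <- counter$k - 1L  # id not consumed
    }
    if (is.null(okTx)) next       # shortfall: budget - nApplied unhonoured
    okTx$node <- nodeId
    sinks[[length(sinks) + 1L]] <- okTx
    recs <- rbind(recs, data.frame(source_id = okTx$source, sink_id = okTx$id,
                                   stringsAsFactors = FALSE))
    nApplied <- nApplied + 1L
  }
  list(sources = c(sources, sinks), sinks = sinks, records = recs,
       nApplied = nApplied, budget = budget)
}

emptyEvents <- function() {
  data.frame(node = character(0), branch = character(0), stage = integer(0),
             event_type = character(0), source_id = character(0),
             sink_id = character(0), payload = character(0),
             stringsAsFactors = FALSE)
}

eventRow <- function(node, branch, stage, type, source, sink, payload = "") {
  data.frame(node = node, branch = branch, stage = stage, event_type = type,
             source_id = source, sink_id = sink, payload = payload,
             stringsAsFactors = FALSE)
}

stageRow <- function(node, branch, stage, type, nSource, budget, nApplied) {
  data.frame(node = node, branch = branch, stage = stage, type = type,
             n_source = nSource, budget = budget, n_applied = nApplied,
             stringsAsFactors = FALSE)
}

#' Simulate the set of transcripts at the root
#'
#' Two steps. Step 1 (random selection): when `tc_rs` is zero a single
#' transcript containing all exons is selected; otherwise the number of
#' transcripts is drawn via [sampleRootTranscriptCount()] (clamped to the
#' pool size) and that many distinct isoforms are drawn uniformly from the
#' `2^m - 1` pool. Step 2: one evolutionary stage per AS type in the fixed
#' order es, me, a5, a3, ir; each stage's budget is
#' `rootEventBudget(n, tc_x)` with `n` the current source-set size, so a
#' transcript created by one stage can undergo events in later stages.
#' Transcript loss does not occur at the root.
#'
#' @param structure the root [GeneStructure-class].
#' @param config a [SpliceSimConfig-class].
#' @return `list(transcripts =, stages =, events =, edges =)` where
#'   `edges` are forest edges `(parent, child, label)` created by the AS
#'   stages.
#' @export
simulateRootTranscripts <- function(structure, config) {
  tc <- config@tc
  node <- structure@nodeId
  m <- length(structure@exonIds)
  events <- emptyEvents()
  stages <- stageRow(character(0), character(0), integer(0), character(0),
                     integer(0), integer(0), integer(0))[0, ]
  edges <- data.frame(parent = character(0), child = character(0),
                      label = character(0), stringsAsFactors = FALSE)
  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  mint <- function() { counter$k <- counter$k + 1L; paste0(node, "#", counter$k) }

  if (tc[["rs"]] == 0) {
    txs <- list(makeTranscript(mint(), node, structure@exonIds))
  } else {
    n <- sampleRootTranscriptCount(1L)
    pool <- isoformPoolSize(m)
    clamped <- min(n, pool)
    iso <- sampleIsoforms(structure, clamped)
    txs <- lapply(iso, function(ex) makeTranscript(mint(), node, ex))
    if (n > pool)
      events <- rbind(events, eventRow(node, NA, 0L, "rs", NA,
                                       NA, sprintf("clamped:%d->%d", n, pool)))
  }
  for (tx in txs)
    events <- rbind(events, eventRow(node, NA, 0L, "rs", NA, tx$id, ""))
  stages <- rbind(stages, stageRow(node, NA, 0L, "rs", NA_integer_,
                                   length(txs), length(txs)))

  stageIdx <- 0L
  for (kind in AS_KINDS) {
    stageIdx <- stageIdx + 1L
    n <- length(txs)
    budget <- rootEventBudget(n, tc[[kind]])
    st <- runEvolutionaryStage(txs, kind, budget, structure, node, counter)
    txs <- st$sources
    if (nrow(st$records)) {
      events <- rbind(events, eventRow(node, NA, stageIdx, kind,
                                       st$records$source_id,
                                       st$records$sink_id, ""))
      edges <- rbind(edges, data.frame(parent = st$records$source_id,
                                       child = st$records$sink_id,
                                       label = kind, stringsAsFactors = FALSE))
    }
    stages <- rbind(stages, stageRow(node, NA, stageIdx, kind, n, budget,
                                     st$nApplied))
  }
  list(transcripts = txs, stages = stages, events = events, edges = edges)
}

#' Propagate a transcript set along a branch
#'
#' Implements the branch process: (1) structural losses — every parent
#' transcript containing an exon lost on the branch is lost; survivors are
#' the conserved transcripts; (2) regulated losses — `eventBudget(n,
#' tc_tl, kTc, c)` conserved transcripts chosen uniformly are lost;
#' (3) gains — `eventBudget(n, tc_rs, kTc, c)` isoforms drawn from the
#' child pool (excluding isoforms already present) are added as new forest
#' roots; (4) one AS stage per type (es, me, a5, a3, ir) exactly as at the
#' root but with branch budgets `eventBudget(n, tc_x, kTc, c)`. Conserved
#' transcripts keep their parent identity while the branch evolves and are
#' finally copied to child-node transcripts through `conserved` edges.
#'
#' @param parentSet list of parent-node transcript records.
#' @param parentStruct,childStruct parent and child [GeneStructure-class];
#'   `childStruct` must be the replay of `structureEvents` on
#'   `parentStruct` (sequence evolution may have been applied on top).
#' @param structureEvents structure event records for the branch.
#' @param branchLength the branch length `c_s_r`.
#' @param config a [SpliceSimConfig-class].
#' @param childNodeId child node label (used to mint transcript ids).
#' @return `list(transcripts =, stages =, events =, edges =, losses =)`.
#' @export
propagateTranscripts <- function(parentSet, parentStruct, childStruct,
                                 structureEvents, branchLength, config,
                                 childNodeId = childStruct@nodeId) {
  tc <- config@tc
  node <- childNodeId
  lostExons <- vapply(Filter(function(e) e$kind == "exon_loss",
                             structureEvents), `[[`, "", "exonId")
  events <- emptyEvents()
  stages <- NULL
  edges <- data.frame(parent = character(0), child = character(0),
                      label = character(0), stringsAsFactors = FALSE)
  losses <- data.frame(id = character(0), branch = character(0),
                       type = character(0), stringsAsFactors = FALSE)
  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  mint <- function() { counter$k <- counter$k + 1L; paste0(node, "#", counter$k) }

  hit <- vapply(parentSet, function(tx) any(tx$exons %in% lostExons), TRUE)
  for (tx in parentSet[hit]) {
    losses <- rbind(losses, data.frame(id = tx$id, branch = node,
                                       type = "structural_loss",
                                       stringsAsFactors = FALSE))
    events <- rbind(events, eventRow(NA, node, 0L, "structural_loss",
                                     tx$id, NA, ""))
  }
  conserved <- parentSet[!hit]
  stages <- rbind(stages, stageRow(NA, node, 0L, "structural_loss",
                                   length(parentSet), NA_integer_, sum(hit)))

  n <- length(conserved)
  tlBudget <- eventBudget(n, tc[["tl"]], config@kTc, branchLength)
  tlTake <- min(tlBudget, n)
  if (tlTake > 0) {
    gone <- sample.int(n, tlTake)
    for (tx in conserved[gone]) {
      losses <- rbind(losses, data.frame(id = tx$id, branch = node,
                                         type = "tl", stringsAsFactors = FALSE))
      events <- rbind(events, eventRow(NA, node, 1L, "tl", tx$id, NA, ""))
    }
    conserved <- conserved[-gone]
  }
  stages <- rbind(stages, stageRow(NA, node, 1L, "tl", n, tlBudget, tlTake))

  n <- length(conserved)
  rsBudget <- eventBudget(n, tc[["rs"]], config@kTc, branchLength)
  existing <- vapply(conserved, txSignature, "")
  iso <- sampleIsoforms(childStruct, rsBudget, excludeSignatures = existing)
  gains <- lapply(iso, function(ex) makeTranscript(mint(), node, ex))
  for (tx in gains)
    events <- rbind(events, eventRow(NA, node, 2L, "rs", NA, tx$id, ""))
  if (length(gains) < rsBudget)
    events <- rbind(events, eventRow(NA, node, 2L, "rs", NA, NA,
                                     sprintf("pool_exhausted:%d<%d",
                                             length(gains), rsBudget)))
  stages <- rbind(stages, stageRow(NA, node, 2L, "rs", n, rsBudget,
                                   length(gains)))
  txs <- c(conserved, gains)

  stageIdx <- 2L
  for (kind in AS_KINDS) {
    stageIdx <- stageIdx + 1L
    nCur <- length(txs)
    budget <- eventBudget(nCur, tc[[kind]], config@kTc, branchLength)
    st <- runEvolutionaryStage(txs, kind, budget, childStruct, node, counter)
    txs <- st$sources
    if (nrow(st$records)) {
      events <- rbind(events, eventRow(NA, node, stageIdx, kind,
                                       st$records$source_id,
                                       st$records$sink_id, ""))
      edges <- rbind(edges, data.frame(parent = st$records$source_id,
                                       child = st$records$sink_id,
                                       label = kind, stringsAsFactors = FALSE))
    }
    stages <- rbind(stages, stageRow(NA, node, stageIdx, kind, nCur, budget,
                                     st$nApplied))
  }

  # finalize: conserved survivors become child-node transcripts
  final <- list()
  for (tx in txs) {
    if (tx$node == node) { final[[length(final) + 1L]] <- tx; next }
    child <- tx
    child$id <- mint()
    child$node <- node
    child$source <- tx$id
    child$origin <- "conserved"
    edges <- rbind(edges, data.frame(parent = tx$id, child = child$id,
                                     label = "conserved",
                                     stringsAsFactors = FALSE))
    events <- rbind(events, eventRow(NA, node, stageIdx + 1L, "conserved",
                                     tx$id, child$id, ""))
    final[[length(final) + 1L]] <- child
  }
  list(transcripts = final, stages = stages, events = events, edges = edges,
       losses = losses)
}
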