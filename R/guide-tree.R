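#' Parse a guide gene tree
#'
#' Reads a rooted gene tree with branch lengths from a Newick or NHX
#' string (or file). NHX comments (`[&&NHX:...]`) are stripped before
#' parsing and retained verbatim in the returned object; they are not
#' interpreted. Internal nodes without labels receive auto-generated
#' preorder labels (`n1`, `n2`, ...) so every simulated gene is
#' addressable. Every non-root edge must carry a branch length (the
#' expected number of substitutions, which scales all event budgets); a
#' root edge length, if present, is ignored.
#'
#' @param text a Newick/NHX string (ignored when `file` is given).
#' @param file path to a Newick/NHX file.
#' @return a validated [GuideTree-class].
#' @examples
#' gt <- parseGuideTree("((A:1.0,B:1.0):0.5,C:1.5);")
#' nodeLabels(gt)
#' @export
parseGuideTree <- function(text = NULL, file = NULL) {
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  if (is.null(text) || !nzchar(trimws(text)))
    stop("empty guide tree input")
  text <- trimws(text)
  # cheap structural scan so malformed input reports the offending position
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' (end of input, position ",
         nchar(text), ")")
  if (!grepl(";\\s*$", text))
    stop("malformed Newick: missing terminal ';' at position ", nchar(text))
  nhx <- unlist(regmatches(text, gregexpr("\\[&&NHX[^]]*\\]", text)))
  clean <- gsub("\\[[^]]*\\]", "", text)
  tr <- tryCatch(ape::read.tree(text = clean),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick: parser returned no tree")
  if (!ape::is.rooted(tr))
    stop("guide tree must be rooted (unrooted trees are rejected)")
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge))
    stop("validation error: every non-root edge must carry a branch length")
  if (any(is.na(tr$edge.length)))
    stop("validation error: every non-root edge must carry a branch length")
  nInt <- tr$Nnode
  if (is.null(tr$node.label)) tr$node.label <- rep("", nInt)
  auto <- which(is.na(tr$node.label) | tr$node.label == "")
  if (length(auto)) tr$node.label[auto] <- paste0("n", auto)
  new("GuideTree", tree = tr, nhx = as.character(nhx))
}

#' Serialize a guide tree to Newick
#'
#' @param gt a [GuideTree-class].
#' @return a single Newick string with branch lengths and node labels.
#' @export
writeGuideTree <- function(gt) {
  ape::write.tree(gt@tree)
}

#' @describeIn parseGuideTree labels of all nodes, tips first then
#'   internal nodes in `phylo` numbering order.
#' @param gt a [GuideTree-class].
#' @export
nodeLabels <- function(gt) c(gt@tree$tip.label, gt@tree$node.label)

#' @describeIn parseGuideTree labels of the leaves.
#' @export
leafLabels <- function(gt) gt@tree$tip.label

rootLabel <- function(gt) {
  tr <- gt@tree
  nodeLabels(gt)[setdiff(tr$edge[, 1], tr$edge[, 2])[1]]
}

# children of a node label, with branch lengths, in edge order
childrenOf <- function(gt, label) {
  tr <- gt@tree
  labs <- nodeLabels(gt)
  idx <- match(label, labs)
  rows <- which(tr$edge[, 1] == idx)
  data.frame(child = labs[tr$edge[rows, 2]],
             length = tr$edge.length[rows], stringsAsFactors = FALSE)
}

# parent label of a non-root node
parentOf <- function(gt, label) {
  tr <- gt@tree
  labs <- nodeLabels(gt)
  idx <- match(label, labs)
  row <- which(tr$edge[, 2] == idx)
  if (!length(row)) return(NA_character_)
  labs[tr$edge[row, 1]]
}

setMethod("show", "GuideTree", function(object) {
  cat(sprintf("GuideTree: %d leaves, %d internal nodes, root '%s'\n",
              length(object@tree$tip.label), object@tree$Nnode,
              rootLabel(object)))
  cat(" ", writeGuideTree(object), "\n")
  if (length(object@nhx))
    cat(sprintf("  %d NHX comment(s) retained (unused)\n", length(object@nhx)))
  invisible(NULL)
})

#' Transcript-event budgets
#'
#' Number of transcripts undergoing one event type during one evolutionary
#' stage. On a branch the anticipated count for event type `x` is
#' `n * tc_x * k_tc * c_s_r` (source-set size times the event proportion,
#' the user constant and the branch length) and the realized count is its
#' ceiling, so any positive expectation yields at least one event. At the
#' root the proportions apply directly: `ceiling(n * tc_x)`.
#'
#' A floating-point guard (`ceiling(x - 1e-9)`) keeps mathematically
#' integral products (e.g. `3 * 0.1 * 10`) from rounding up one too many.
#'
#' @param n number of source transcripts at the stage.
#' @param proportion the event-type proportion `tc_x`.
#' @param kTc the user constant factor.
#' @param branchLength the branch length `c_s_r`.
#' @return integer event count.
#' @examples
#' eventBudget(7, 0.1, 1, 1)   # 1
#' rootEventBudget(2, 0.3)     # 1
#' @export
eventBudget <- function(n, proportion, kTc, branchLength) {
  stopifnot(length(n) == 1, length(proportion) == 1)
  if (n < 0 || proportion < 0 || kTc < 0 || branchLength < 0)
    stop("domain error: event_budget arguments must be >= 0")
  x <- as.numeric(n) * proportion * kTc * branchLength
  if (x <= 0) return(0L)
  as.integer(ceiling(x - 1e-9))
}

#' @rdname eventBudget
#' @export
rootEventBudget <- function(n, proportion) {
  if (n < 0 || proportion < 0)
    stop("domain error: root_event_budget arguments must be >= 0")
  x <- as.numeric(n) * proportion
  if (x <= 0) return(0L)
  as.integer(ceiling(x - 1e-9))
}
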