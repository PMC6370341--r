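# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards: every stochastic operation is a pure function of
# (inputs, seed) and never disturbs global randomness.
.withSeed <- function(seed, expr) {
  if (missing(seed) || is.null(seed) || length(seed) != 1L ||
      !is.finite(seed)) {
    stop("a single finite integer 'seed' is required for stochastic operations")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# round-half-up (reports use 59/61 -> 97, 59/81 -> 73; base round() is
# round-half-even and would disagree on .5 boundaries)
.roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

.checkTree <- function(tree) {
  if (!inherits(tree, "phylo")) {
    stop("'tree' must be an ape \"phylo\" object")
  }
  if (is.null(tree$edge.length)) {
    stop("'tree' must have branch lengths")
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length in tree")
  }
  invisible(tree)
}

# children of every node, indexed by node number
.childList <- function(tree) {
  n <- max(tree$edge)
  kids <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  kids
}

# edge index leading into each node (NA for the root)
.parentEdge <- function(tree) {
  n <- max(tree$edge)
  pe <- rep(NA_integer_, n)
  pe[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  pe
}

# internal node numbers in postorder (children before parents)
.postorderNodes <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  unique(po$edge[, 1L])
}
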