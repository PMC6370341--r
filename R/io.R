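# Readers/writers for the standard formats the pipeline touches, plus
# shared tree utilities.  FASTA goes through Biostrings, Newick and NEXUS
# through ape; the wrappers enforce the invariants the downstream analyses
# rely on (equal-width alignments, unique ids, binary character states).

#' Read a gapped nucleotide alignment from FASTA
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique names, all sequences of
#'   equal length, residues uppercased.  Input record order is preserved.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "AC-T"), f)
#' readFastaAlignment(f)
#' @export
readFastaAlignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path)
  # keep the id token only, as alignment tools do
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    stop("duplicate sequence id: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  w <- Biostrings::width(x)
  if (length(unique(w)) != 1L) {
    bad <- names(x)[w != w[1L]][1L]
    stop("ragged alignment: record '", bad, "' has length ",
         w[names(x) == bad][1L], ", expected ", w[1L])
  }
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write an alignment to FASTA
#'
#' @param aln a \code{DNAStringSet} or named character vector.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeFastaAlignment <- function(aln, path) {
  if (is.character(aln)) aln <- Biostrings::DNAStringSet(aln)
  Biostrings::writeXStringSet(aln, path)
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] and [ape::write.tree()] that
#' check parenthesis balance up front (reporting the character position of
#' the imbalance) and preserve branch lengths to 10 significant digits on a
#' round trip.  Quoted labels are supported by ape; internal-node labels
#' (e.g. support values) are carried along but unused.
#'
#' @param path file path.
#' @return \code{readNewick}: an ape \code{phylo}.
#' @export
readNewick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("Newick parse error: unmatched ')' at position ", i)
    }
  }
  if (depth != 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' at end of input")
  }
  tree <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("Newick parse error in ", path)
  }
  tree
}

#' @rdname readNewick
#' @param tree an ape \code{phylo}.
#' @return \code{writeNewick}: invisibly, \code{path}.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read a Mesquite-style NEXUS file with a binary character matrix
#'
#' Parses the TAXA and CHARACTERS blocks (and, when present, a TREES
#' block).  Only binary characters are supported: state symbols other than
#' 0, 1 and the missing symbols "?" and "-" are an error.  Both "?" and "-"
#' are mapped to missing (NA), as Mesquite accepts both.
#'
#' @param path path to a NEXUS file.
#' @return A list with elements \code{states} (a numeric matrix, taxa as
#'   rows in TAXLABELS order, one column per character, entries 0/1/NA) and
#'   \code{tree} (an ape \code{phylo}, or NULL when the file has no TREES
#'   block).
#' @export
readNexusCharacters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  up <- toupper(txt)

  dat <- ape::read.nexus.data(path)
  states <- do.call(rbind, lapply(dat, function(v) {
    v <- toupper(v)
    bad <- setdiff(unique(v), c("0", "1", "?", "-"))
    if (length(bad)) {
      stop("non-binary state symbol in character matrix: ",
           paste(bad, collapse = ", "))
    }
    out <- rep(NA_real_, length(v))
    out[v == "0"] <- 0
    out[v == "1"] <- 1
    out
  }))
  rownames(states) <- names(dat)
  colnames(states) <- paste0("char", seq_len(ncol(states)))

  # validate against TAXLABELS when a TAXA block is present
  lab_ln <- grep("TAXLABELS", up)
  if (length(lab_ln)) {
    end_ln <- grep(";", up)
    end_ln <- end_ln[end_ln >= lab_ln[1L]][1L]
    block <- paste(txt[lab_ln[1L]:end_ln], collapse = " ")
    block <- sub(".*TAXLABELS", "", block, ignore.case = TRUE)
    block <- sub(";.*", "", block)
    taxa <- regmatches(block, gregexpr("'[^']+'|[^\\s']+", block,
                                       perl = TRUE))[[1L]]
    taxa <- gsub("^'|'$", "", taxa)
    taxa <- taxa[nzchar(taxa)]
    extra <- setdiff(rownames(states), taxa)
    if (length(extra)) {
      stop("taxa in CHARACTERS block absent from TAXA block: ",
           paste(extra, collapse = ", "))
    }
    states <- states[taxa[taxa %in% rownames(states)], , drop = FALSE]
  }

  tree <- NULL
  if (any(grepl("BEGIN\\s+TREES", up))) {
    tr <- tryCatch(ape::read.nexus(path), error = function(e) NULL)
    if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
    tree <- tr
  }
  list(states = states, tree = tree)
}

#' Root a tree at the midpoint of its longest leaf-to-leaf path
#'
#' @param tree an ape \code{phylo} with branch lengths (rooted or
#'   unrooted); the leaf set is unchanged.
#' @return A rooted \code{phylo} whose two maximal root-to-leaf distances
#'   are equal (to within 1e-9 of the tree diameter).
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:3):0,c:0);")
#' midpointRoot(tr)
#' @export
midpointRoot <- function(tree) {
  .checkTree(tree)
  if (ape::Ntip(tree) < 2L) stop("midpoint rooting needs at least 2 leaves")
  if (sum(tree$edge.length) <= 0) stop("degenerate tree: all branch lengths zero")
  phangorn::midpoint(tree)
}
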