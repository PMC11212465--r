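#' Read a tree from a newick file
#'
#' Thin wrapper around [ape::read.tree()] that fails loudly on malformed
#' input. Internal-node labels (bootstrap supports) are preserved.
#'
#' @param path Path to a newick file (one tree, or several on separate lines).
#' @return A `phylo` object, or a `multiPhylo` if the file holds several trees.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("newick file not found: ", path)
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tr)) stop("malformed newick in ", path)
  tr
}

#' Write a tree (or trees) to a newick file
#'
#' @param tree A `phylo` or `multiPhylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read an aligned FASTA file into a character matrix
#'
#' Rows are records in file order, row names are record ids. Sequences are
#' upper-cased. Duplicate ids are an error.
#'
#' @param path Path to a FASTA file.
#' @return Character matrix (taxa x sites) of single characters.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  rec <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  seqs <- toupper(seqs)
  n <- nchar(seqs)
  if (length(unique(n)) != 1L) {
    stop("sequences are not aligned (unequal lengths) in ", path)
  }
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- ids
  m
}

#' Write a character-matrix alignment to FASTA
#'
#' @param seqs Character matrix (taxa x sites) or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.matrix(seqs)) {
    ids <- rownames(seqs)
    txt <- apply(seqs, 1L, paste, collapse = "")
  } else {
    ids <- names(seqs)
    txt <- seqs
  }
  if (is.null(ids)) stop("sequences must be named")
  if (anyDuplicated(ids)) stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", ids, "\n", toupper(txt)), con)
  invisible(path)
}
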