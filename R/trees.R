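#' Read a set of trees from a Newick file
#'
#' One tree per line or ';'-separated. Branch lengths default to 0 when
#' absent; numeric internal-node labels are interpreted as support values
#' (RAxML-style dialect).
#'
#' @param path Newick file path.
#' @return A `multiPhylo` with attribute `taxon_universe` (union of leaf
#'   sets).
#' @export
read_treeset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  trees <- list()
  for (ln in seq_along(lines)) {
    txt <- trimws(lines[ln])
    if (!nzchar(txt)) next
    pieces <- strsplit(txt, ";", fixed = TRUE)[[1]]
    for (piece in pieces) {
      piece <- trimws(piece)
      if (!nzchar(piece)) next
      if (.paren_balance(piece) != 0) {
        stop("unbalanced parentheses in Newick at line ", ln)
      }
      tr <- tryCatch(ape::read.tree(text = paste0(piece, ";")),
                     error = function(e) NULL)
      if (is.null(tr)) stop("could not parse Newick at line ", ln)
      if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
      trees[[length(trees) + 1L]] <- tr
    }
  }
  if (!length(trees)) stop("no trees in ", path)
  ts <- structure(trees, class = "multiPhylo")
  attr(ts, "taxon_universe") <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  ts
}

.paren_balance <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  sum(chars == "(") - sum(chars == ")")
}

#' Write a set of trees to Newick
#'
#' One tree per line; internal-node labels (e.g. supports) are emitted when
#' present.
#'
#' @param ts A `multiPhylo` (or single `phylo`, or list of `phylo`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_treeset <- function(ts, path) {
  ts <- as_treeset(ts)
  txt <- vapply(ts, function(tr) ape::write.tree(tr), character(1))
  writeLines(txt, path)
  invisible(path)
}

#' Coerce to a tree set
#'
#' @param x A `phylo`, `multiPhylo`, or list of `phylo`.
#' @return A `multiPhylo` with `taxon_universe` attribute.
#' @export
as_treeset <- function(x) {
  if (inherits(x, "phylo")) x <- list(x)
  if (!inherits(x, "multiPhylo")) {
    stopifnot(all(vapply(x, inherits, logical(1), "phylo")))
    x <- structure(x, class = "multiPhylo")
  }
  if (is.null(attr(x, "taxon_universe"))) {
    attr(x, "taxon_universe") <- sort(unique(unlist(lapply(x, `[[`, "tip.label"))))
  }
  x
}

#' Remove taxa from an alignment or tree set
#'
#' Alignment rows are dropped; tree leaves are pruned with the resulting
#' degree-2 nodes suppressed (their branch lengths summed, ape's behaviour).
#'
#' @param x A [phy_alignment], `phylo`, or `multiPhylo`.
#' @param taxa Labels to remove.
#' @return Object of the same kind.
#' @export
remove_taxa <- function(x, taxa) UseMethod("remove_taxa")

#' @export
remove_taxa.phy_alignment <- function(x, taxa) {
  if (!length(taxa)) return(x)
  unknown <- setdiff(taxa, x$taxa)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  keep <- setdiff(x$taxa, taxa)
  if (length(keep) < 4) stop("removal would leave fewer than 4 taxa")
  out <- x
  out$seq <- x$seq[keep, , drop = FALSE]
  out$taxa <- keep
  out
}

#' @export
remove_taxa.phylo <- function(x, taxa) {
  if (!length(taxa)) return(x)
  pres <- intersect(taxa, x$tip.label)
  if (length(x$tip.label) - length(pres) < 4) {
    stop("removal would leave fewer than 4 leaves")
  }
  if (!length(pres)) return(x)
  ape::drop.tip(x, pres)
}

#' @export
remove_taxa.multiPhylo <- function(x, taxa) {
  out <- lapply(x, remove_taxa, taxa = taxa)
  as_treeset(out)
}
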