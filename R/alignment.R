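#' Multiple sequence alignment container
#'
#' A `phy_alignment` is a taxa x columns character matrix plus partition
#' bookkeeping. Partitions are named, disjoint sets of column indices, each
#' carrying its own alphabet ("dna" or "aa"), so concatenated
#' nucleotide+protein datasets live in one object. Each column remembers its
#' original (1-based) column number, preserved through site stripping so that
#' removal manifests can always be stated in original coordinates.
#'
#' @param seqs Named character vector of sequences, or a character matrix
#'   (rows = taxa, one character per cell) with rownames.
#' @param alphabet "dna", "aa", or "auto" (detect from residues).
#' @param partitions Named list of integer column-index vectors, or NULL for
#'   a single partition spanning all columns (named after `alphabet`).
#' @param source_index Original 1-based column numbers (default 1:ncol).
#' @return An object of class `phy_alignment`.
#' @export
phy_alignment <- function(seqs, alphabet = "auto", partitions = NULL,
                          source_index = NULL) {
  if (!is.matrix(seqs)) {
    labels <- names(seqs)
    if (is.null(labels)) stop("sequences must be named")
    n <- nchar(seqs)
    if (length(unique(n)) > 1) {
      bad <- names(seqs)[n != n[1]][1]
      stop("ragged alignment: sequence lengths differ (taxon '", bad, "')")
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- labels
  } else {
    m <- seqs
    m[] <- toupper(m)
  }
  if (is.null(rownames(m))) stop("alignment must have taxon labels")
  labels <- trimws(rownames(m))
  if (anyDuplicated(labels)) {
    stop("duplicate taxon labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  rownames(m) <- labels
  if (identical(alphabet, "auto")) {
    resid <- setdiff(unique(as.vector(m)), c("-", "?", "."))
    alphabet <- if (all(resid %in% names(DNA_AMBIG))) "dna" else "aa"
  }
  if (alphabet == "dna") m[m == "U"] <- "T"
  nc <- ncol(m)
  if (is.null(partitions)) {
    partitions <- stats::setNames(list(seq_len(nc)), alphabet)
    part_alpha <- stats::setNames(alphabet, alphabet)
  } else {
    part_alpha <- vapply(partitions, function(p) attr(p, "alphabet") %||% alphabet,
                         character(1))
    partitions <- lapply(partitions, function(p) as.integer(p))
    idx <- unlist(partitions, use.names = FALSE)
    if (anyDuplicated(idx) || any(idx < 1 | idx > nc)) {
      stop("partitions must be disjoint column sets within the alignment")
    }
  }
  structure(list(
    seq = m,
    taxa = labels,
    alphabet = alphabet,
    partitions = partitions,
    part_alphabet = part_alpha,
    source_index = as.integer(source_index %||% seq_len(nc))
  ), class = "phy_alignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.phy_alignment <- function(x, ...) {
  cat("phy_alignment:", nrow(x$seq), "taxa x", ncol(x$seq), "columns\n")
  for (p in names(x$partitions)) {
    cat("  partition '", p, "' (", x$part_alphabet[[p]], "): ",
        length(x$partitions[[p]]), " columns\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.phy_alignment <- function(x) dim(x$seq)

#' Read a multiple sequence alignment
#'
#' Reads FASTA or relaxed sequential PHYLIP into a [phy_alignment].
#' Characters are upper-cased; for DNA, U is mapped to T. All sequences
#' must have equal length and unique labels.
#'
#' @param path File path.
#' @param format "fasta" or "phylip" ("auto" inspects the first character).
#' @param alphabet "dna", "aa" or "auto".
#' @return A [phy_alignment] with a single partition covering all columns.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip"),
                           alphabet = "auto") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- substr(trimws(readLines(path, n = 1L)), 1, 1)
    format <- if (first == ">") "fasta" else "phylip"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- stats::setNames(as.character(ss), trimws(names(ss)))
  } else {
    seqs <- .read_phylip(path)
  }
  n <- nchar(seqs)
  if (length(unique(n)) > 1) {
    ## the first record defines the expected width
    bad <- names(seqs)[n != n[1]][1]
    stop("ragged alignment in ", path, ": taxon '", bad,
         "' has length ", nchar(seqs[bad]), ", expected ", n[1])
  }
  phy_alignment(seqs, alphabet = alphabet)
}

## relaxed sequential PHYLIP: header "ntaxa nsites", then one
## whitespace-separated "label sequence" record per taxon (sequence may
## continue on following lines until nsites characters are collected)
.read_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- scan(text = lines[1], what = integer(), n = 2, quiet = TRUE)
  if (length(hdr) != 2) stop("malformed PHYLIP header in ", path)
  ntax <- hdr[1]; nsite <- hdr[2]
  seqs <- character(0)
  i <- 2
  for (t in seq_len(ntax)) {
    if (i > length(lines)) stop("PHYLIP file truncated: expected ", ntax, " taxa")
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    label <- parts[1]
    seq <- paste(parts[-1], collapse = "")
    i <- i + 1
    while (nchar(seq) < nsite && i <= length(lines)) {
      seq <- paste0(seq, gsub("\\s", "", lines[i]))
      i <- i + 1
    }
    seqs[label] <- seq
  }
  if (any(nchar(seqs) != nsite)) {
    bad <- names(seqs)[nchar(seqs) != nsite][1]
    stop("PHYLIP sequence length mismatch for taxon '", bad, "'")
  }
  seqs
}

#' Write a multiple sequence alignment
#'
#' @param aln A [phy_alignment].
#' @param path Output file path.
#' @param format "fasta" or "phylip".
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "phy_alignment"))
  seqs <- apply(aln$seq, 1, paste, collapse = "")
  if (format == "fasta") {
    writeLines(paste0(">", names(seqs), "\n", seqs), path)
  } else {
    writeLines(c(paste(length(seqs), ncol(aln$seq)),
                 paste(names(seqs), seqs)), path)
  }
  invisible(path)
}

#' Write the sidecar site map
#'
#' TSV with columns `kept_index`, `original_index`, `partition`, recording
#' where each current column came from in the original alignment. Written
#' alongside stripped alignments so site-removal is auditable.
#'
#' @param aln A [phy_alignment].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_site_map <- function(aln, path) {
  part <- character(ncol(aln$seq))
  for (p in names(aln$partitions)) part[aln$partitions[[p]]] <- p
  df <- data.frame(kept_index = seq_len(ncol(aln$seq)),
                   original_index = aln$source_index,
                   partition = part)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Concatenate alignments into a partitioned dataset
#'
#' Columns are appended in the given order and each input becomes a named
#' partition. Taxa missing from a part are filled with gaps there and listed
#' in the `missing_report` attribute.
#'
#' @param parts Named list of [phy_alignment] objects.
#' @return A [phy_alignment] with one partition per input part.
#' @export
concatenate <- function(parts) {
  stopifnot(length(parts) >= 1, !is.null(names(parts)))
  if (length(parts) == 1) {
    out <- parts[[1]]
    names(out$partitions) <- names(parts)
    names(out$part_alphabet) <- names(parts)
    attr(out, "missing_report") <- data.frame(taxon = character(0),
                                              partition = character(0))
    return(out)
  }
  taxa <- Reduce(union, lapply(parts, function(a) a$taxa))
  widths <- vapply(parts, function(a) ncol(a$seq), integer(1))
  total <- sum(widths)
  m <- matrix("-", length(taxa), total, dimnames = list(taxa, NULL))
  partitions <- list()
  src <- integer(0)
  missing <- data.frame(taxon = character(0), partition = character(0))
  off <- 0L
  part_alpha <- character(0)
  for (nm in names(parts)) {
    a <- parts[[nm]]
    cols <- off + seq_len(ncol(a$seq))
    m[a$taxa, cols] <- a$seq
    absent <- setdiff(taxa, a$taxa)
    if (length(absent)) {
      missing <- rbind(missing, data.frame(taxon = absent, partition = nm))
    }
    partitions[[nm]] <- cols
    part_alpha[nm] <- a$alphabet
    src <- c(src, a$source_index)
    off <- off + ncol(a$seq)
  }
  out <- phy_alignment(m, alphabet = if (all(part_alpha == "dna")) "dna" else
                         if (all(part_alpha == "aa")) "aa" else "mixed",
                       partitions = partitions, source_index = src)
  out$part_alphabet <- part_alpha
  attr(out, "missing_report") <- missing
  out
}

#' Extract one partition as a stand-alone alignment
#'
#' @param aln A [phy_alignment].
#' @param name Partition name.
#' @return A [phy_alignment] with a single partition.
#' @export
get_partition <- function(aln, name) {
  stopifnot(name %in% names(aln$partitions))
  cols <- aln$partitions[[name]]
  phy_alignment(aln$seq[, cols, drop = FALSE],
                alphabet = aln$part_alphabet[[name]],
                source_index = aln$source_index[cols])
}

## cheap content fingerprint used to guard classification/alignment pairing
.aln_checksum <- function(aln) {
  tab <- table(factor(as.vector(aln$seq[, seq(1, ncol(aln$seq),
                                              length.out = min(ncol(aln$seq), 200))])))
  paste(nrow(aln$seq), ncol(aln$seq),
        paste(names(tab), as.integer(tab), collapse = ","), sep = "|")
}
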