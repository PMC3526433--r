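# -------------------------------------------------------------------------
# Multi-gene alignment sets.
#
# A gene_alignments object holds k per-gene DNA alignments over a common
# taxon set. Sequences are stored as integer bitmask matrices
# (A=1, C=2, G=4, T=8; IUPAC ambiguity codes are unions of bits; gaps and
# N are fully missing, 15) and site patterns are compressed once at
# construction: each distinct site column is kept with a multiplicity
# weight, which is what the pruning kernel consumes.
# -------------------------------------------------------------------------

iupac_codes <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L, `-` = 15L, `?` = 15L,
  `.` = 15L)

encode_gene <- function(g) {
  if (is.matrix(g) && is.character(g)) {
    m <- toupper(g)
  } else if (is.character(g)) {
    if (is.null(names(g))) stop("sequences must be named by taxon")
    sp <- strsplit(toupper(g), "")
    if (length(unique(lengths(sp))) != 1L) {
      stop("sequences within a gene must have equal length")
    }
    m <- do.call(rbind, sp)
    rownames(m) <- names(g)
  } else {
    stop("each gene must be a character matrix or named character vector")
  }
  code <- iupac_codes[m]
  code[is.na(code)] <- 15L  # unknown characters treated as missing
  enc <- matrix(as.integer(code), nrow = nrow(m),
                dimnames = list(rownames(m), NULL))
  enc
}

#' Build a multi-gene alignment set
#'
#' Assembles the per-gene alignments `S = {S_1, ..., S_k}` used by the
#' network likelihood. All genes must share the same taxon set; site
#' patterns are compressed at construction.
#'
#' @param genes A list of per-gene alignments; each element is either a
#'   character matrix (rows = taxa, single characters) or a named
#'   character vector of sequences. Gaps, `N` and any non-IUPAC character
#'   are treated as missing data.
#' @param names Optional gene names (defaults to `gene1..geneK`).
#' @return A `gene_alignments` object with fields `genes` (encoded
#'   matrices), `taxa`, `lengths` (sites per gene), `n` (total sites) and
#'   `k` (number of genes).
#' @export
gene_alignments <- function(genes, names = NULL) {
  if (!is.list(genes) || !length(genes)) stop("need a nonempty list of genes")
  enc <- lapply(genes, encode_gene)
  taxa <- sort(rownames(enc[[1]]))
  if (anyDuplicated(taxa)) stop("duplicated taxon names")
  for (e in enc) {
    if (!setequal(rownames(e), taxa)) {
      stop("all genes must share the same taxon set")
    }
  }
  enc <- lapply(enc, function(e) e[taxa, , drop = FALSE])
  if (is.null(names)) names <- sprintf("gene%d", seq_along(enc))
  lengths <- vapply(enc, ncol, 0L)
  if (any(lengths == 0L)) stop("empty alignment")
  # site patterns compressed globally: distinct columns over all genes,
  # with a per-gene multiplicity matrix (patterns x genes)
  all <- do.call(cbind, enc)
  key <- apply(all, 2, paste, collapse = ",")
  u <- !duplicated(key)
  pat <- all[, u, drop = FALSE]
  pidx <- match(key, key[u])
  gidx <- rep(seq_along(enc), lengths)
  # sparse (pattern, gene) multiplicities for per-gene aggregation
  wkey <- (pidx - 1) * length(enc) + gidx
  uw <- !duplicated(wkey)
  cnt <- as.numeric(table(factor(wkey, levels = wkey[uw])))
  patT <- t(pat)
  storage.mode(patT) <- "integer"
  obj <- structure(list(
    genes = enc,
    gene_names = names,
    taxa = taxa,
    lengths = lengths,
    n = sum(lengths),
    k = length(enc),
    pat = pat,
    patT = patT,
    w_pat = pidx[uw],
    w_gene = gidx[uw],
    w_cnt = cnt
  ), class = "gene_alignments")
  obj$id <- alignment_id(obj)
  obj
}

# cheap content fingerprint used as part of likelihood cache keys
alignment_id <- function(x) {
  v <- as.double(x$pat) * rep_len(c(1.0, 2.654435769, 7.7180339887),
                                  length(x$pat))
  sprintf("ga_%d_%d_%.0f", x$k, x$n, sum(v) * 1000)
}

#' @export
print.gene_alignments <- function(x, ...) {
  cat(sprintf("Gene alignment set: %d genes, %d taxa, %d total sites\n",
              x$k, length(x$taxa), x$n))
  cat(sprintf("Sites per gene: %s\n",
              paste(utils::head(x$lengths, 10), collapse = ", ")))
  invisible(x)
}

#' @export
`[.gene_alignments` <- function(x, i) {
  dec <- decode_genes(x)[i]
  gene_alignments(dec, names = x$gene_names[i])
}

decode_genes <- function(x) {
  bases <- c("A", "C", "G", "T")
  lapply(x$genes, function(e) {
    m <- matrix("N", nrow(e), ncol(e), dimnames = dimnames(e))
    for (b in 1:4) m[e == bitwShiftL(1L, b - 1L)] <- bases[b]
    m
  })
}

# ---- readers / writers --------------------------------------------------

read_fasta_matrix <- function(path) {
  d <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(d)))
  m
}

read_relaxed_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  ntax <- hdr[1]; nsite <- hdr[2]
  seqs <- character(0)
  for (ln in lines[-1][seq_len(ntax)]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    seqs[parts[1]] <- gsub("\\s", "", paste(parts[-1], collapse = ""))
  }
  if (any(nchar(seqs) != nsite)) stop("PHYLIP sequence length mismatch in ", path)
  seqs
}

#' Read a set of gene alignments from files
#'
#' Reads FASTA or relaxed (whitespace-delimited) PHYLIP alignments, one
#' file per gene, either from a vector of paths or from a manifest TSV
#' with columns `gene_id` and `path` (paths resolved relative to the
#' manifest's directory).
#'
#' @param paths Character vector of alignment files, or a single path to a
#'   manifest TSV.
#' @return A `gene_alignments` object.
#' @export
read_gene_alignments <- function(paths) {
  if (length(paths) == 1L && grepl("\\.tsv$", paths)) {
    man <- utils::read.delim(paths, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "path") %in% names(man))) {
      stop("manifest must have columns gene_id and path")
    }
    files <- file.path(dirname(paths), man$path)
    names <- man$gene_id
  } else {
    files <- paths
    names <- sub("\\.[^.]*$", "", basename(paths))
  }
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("alignment file not found: ", paste(missing, collapse = ", "))
  }
  genes <- lapply(files, function(f) {
    first <- readChar(f, 1L)
    if (identical(first, ">")) read_fasta_matrix(f) else read_relaxed_phylip(f)
  })
  gene_alignments(genes, names = names)
}

#' Write gene alignments as FASTA files plus a manifest
#'
#' One FASTA file per gene is written into `dir`, together with a
#' `manifest.tsv` (columns `gene_id`, `path`, `length`) that
#' [read_gene_alignments()] can consume.
#'
#' @param x A `gene_alignments` object.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_gene_alignments <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dec <- decode_genes(x)
  paths <- sprintf("%s.fasta", x$gene_names)
  for (i in seq_along(dec)) {
    m <- dec[[i]]
    con <- file.path(dir, paths[i])
    out <- character(2L * nrow(m))
    out[c(TRUE, FALSE)] <- paste0(">", rownames(m))
    out[c(FALSE, TRUE)] <- apply(m, 1, paste, collapse = "")
    writeLines(out, con)
  }
  man <- file.path(dir, "manifest.tsv")
  utils::write.table(
    data.frame(gene_id = x$gene_names, path = paths, length = x$lengths),
    man, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(man)
}
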