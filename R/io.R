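#' Read an orthogroup table (Orthogroups.tsv dialect)
#'
#' Parses the tab-separated orthogroup format produced by orthology
#' clustering tools: a header row of organism names, then one row per
#' orthogroup with the orthogroup id in the first column and a ", "-joined
#' gene list per organism column. An empty cell means the organism has no
#' gene in that orthogroup.
#'
#' @param path Path to the TSV file.
#' @param organisms An `organism_set`; every header column must resolve to a
#'   declared organism id (case-sensitive) and every declared organism must
#'   appear in the header.
#' @return An object of class `orthogroup_table`: a named list mapping
#'   orthogroup id to a named list of character vectors (organism -> genes).
#' @export
read_orthogroups <- function(path, organisms) {
  stopifnot(inherits(organisms, "organism_set"))
  lines <- readLines(path)
  if (!length(lines)) stop("empty orthogroup file: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  orgs <- header[-1]
  unknown <- setdiff(orgs, organisms$id)
  if (length(unknown))
    stop("orthogroup table has unknown organism column(s): ",
         paste(unknown, collapse = ", "))
  absent <- setdiff(organisms$id, orgs)
  if (length(absent))
    stop("organism ", paste(absent, collapse = ", "),
         " missing from orthogroup table header")

  body <- lines[-1]
  body <- body[nzchar(body)]
  out <- vector("list", length(body))
  ids <- character(length(body))
  for (i in seq_along(body)) {
    cells <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    length(cells) <- length(header)  # pad trailing empty cells
    cells[is.na(cells)] <- ""
    ids[i] <- cells[[1]]
    genes <- lapply(cells[-1], function(cell) {
      if (!nzchar(trimws(cell))) character(0)
      else trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
    })
    names(genes) <- orgs
    out[[i]] <- genes
  }
  if (anyDuplicated(ids))
    stop("duplicated orthogroup id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(out) <- ids

  all_genes <- unlist(out, use.names = FALSE)
  if (anyDuplicated(all_genes))
    stop("gene(s) assigned to more than one orthogroup: ",
         paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "))
  structure(out, class = "orthogroup_table", organisms = orgs)
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat("Orthogroup table:", length(x), "orthogroups,",
      length(attr(x, "organisms")), "organisms\n")
  invisible(x)
}

#' Write an orthogroup table in Orthogroups.tsv dialect
#'
#' @param x An `orthogroup_table` (or compatible named list of named lists).
#' @param path Output path.
#' @export
write_orthogroups <- function(x, path) {
  orgs <- attr(x, "organisms")
  if (is.null(orgs)) orgs <- names(x[[1]])
  rows <- vapply(names(x), function(og) {
    cells <- vapply(orgs, function(o)
      paste(x[[og]][[o]], collapse = ", "), character(1))
    paste(c(og, cells), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("Orthogroup", orgs), collapse = "\t"), rows), path)
  invisible(path)
}

#' Read tabular protein homology hits
#'
#' Reads BLAST tabular output in the 14-column dialect
#' `-outfmt "6 std qlen slen"`. Query and subject sequence lengths are
#' required because alignment coverage is computed from them; the standard
#' 12-column format is rejected with instructions.
#'
#' @param path Path to the tab-separated hit table (no header).
#' @return A data frame of class `blast_hits` with columns `query`,
#'   `subject`, `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`, `qlen`, `slen`, and a logical
#'   `self` flag marking query == subject rows (retained, not dropped).
#' @export
read_blast_tabular <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty homology hit file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol == 12L))
    stop("12-column tabular input detected (no qlen/slen): rerun the search ",
         "with -outfmt \"6 std qlen slen\" or provide a sequence-lengths ",
         "table so that coverage can be computed")
  bad <- which(ncol != 14L)
  if (length(bad))
    stop("line ", bad[1], ": expected 14 tab-separated columns, found ",
         ncol[bad[1]])
  m <- do.call(rbind, fields)
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "qlen", "slen")
  df <- data.frame(m, stringsAsFactors = FALSE)
  names(df) <- cols
  num_cols <- cols[-(1:2)]
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("line ", bad, ": malformed numeric value '", df[[cc]][bad],
           "' in column ", cc)
    }
    df[[cc]] <- v
  }
  if (any(df$bitscore < 0)) stop("negative bit score encountered")
  if (any(df$pident < 0 | df$pident > 100))
    stop("percent identity outside [0, 100]")
  if (any(df$qlen <= 0 | df$slen <= 0))
    stop("non-positive sequence length encountered")
  df$self <- df$query == df$subject
  class(df) <- c("blast_hits", "data.frame")
  df
}

#' Write homology hits in 14-column tabular format
#'
#' @param hits A `blast_hits` data frame.
#' @param path Output path.
#' @export
write_blast_tabular <- function(hits, path) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "qlen", "slen")
  utils::write.table(hits[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-organism TPM tables into an expression matrix
#'
#' Each organism's table is a TSV with gene ids in the first column and one
#' column per replicate sample. Genes absent from an organism's table are
#' recorded as missing (`NA`) for that organism -- distinct from an observed
#' TPM of 0, which matters for orthogroup occupancy logic.
#'
#' @param sheet A `sample_sheet` mapping samples to organisms and files.
#' @param pseudocount Pseudocount stored for later log transformation
#'   (default 0.01).
#' @return An `expression_matrix` (see [expression_matrix()]) with the
#'   replicate layer filled and per-organism averages computed.
#' @export
read_tpm_tables <- function(sheet, pseudocount = 0.01) {
  stopifnot(inherits(sheet, "sample_sheet"))
  paths <- unique(sheet$path)
  tabs <- lapply(paths, function(p) {
    df <- utils::read.delim(p, stringsAsFactors = FALSE, check.names = FALSE)
    gid <- as.character(df[[1]])
    if (anyDuplicated(gid))
      stop("duplicated gene id(s) in ", p, ": ",
           paste(unique(gid[duplicated(gid)]), collapse = ", "))
    vals <- as.matrix(df[-1])
    if (!is.numeric(vals)) stop("non-numeric TPM values in ", p)
    if (any(vals < 0, na.rm = TRUE))
      stop("negative TPM value in ", p)
    rownames(vals) <- gid
    vals
  })
  names(tabs) <- paths

  genes <- sort(unique(unlist(lapply(tabs, rownames))))
  reps <- matrix(NA_real_, length(genes), nrow(sheet),
                 dimnames = list(genes, sheet$sample))
  for (i in seq_len(nrow(sheet))) {
    tab <- tabs[[sheet$path[i]]]
    if (!sheet$sample[i] %in% colnames(tab))
      stop("sample column '", sheet$sample[i], "' not found in ",
           sheet$path[i])
    reps[rownames(tab), sheet$sample[i]] <- tab[, sheet$sample[i]]
  }
  expression_matrix(reps, sheet[c("sample", "organism", "replicate")],
                    pseudocount = pseudocount)
}

#' Newick input/output for expression trees
#'
#' Thin wrappers around the `ape` tree readers/writers so that trees with
#' branch lengths and internal-node support labels round-trip losslessly.
#'
#' @param tree An object of class `phylo`.
#' @param path File path.
#' @return `read_newick` returns a `phylo`; `write_newick` invisibly returns
#'   `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in ", path)
  tree
}
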