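#' Define the set of organisms under study
#'
#' The comparative framework treats every expression source as an "organism":
#' true diploid species, the two subgenomes of each allotetraploid (each
#' subgenome is analysed as an independent organism), and at most one
#' outgroup species used to root trees and reference relative-rate tests.
#'
#' @param ids Character vector of unique organism identifiers
#'   (e.g. `"A1"`, `"D5"`, `"At1"`, `"Tcacao"`).
#' @param roles Character vector, same length as `ids`; each element one of
#'   `"diploid"`, `"subgenome"`, `"outgroup"`.
#' @param subgenome_parent Named character vector mapping each subgenome id
#'   to its tetraploid id (e.g. `c(At1 = "AD1", Dt1 = "AD1")`). Required when
#'   any role is `"subgenome"`.
#' @param labels Optional named character vector of display labels.
#'
#' @return An object of class `organism_set`: a data frame with columns
#'   `id`, `role`, `parent` (tetraploid id, `NA` for non-subgenomes) and
#'   `label`.
#' @examples
#' organism_set(c("A1", "A2", "D5", "At1", "Dt1", "Tcacao"),
#'              c("diploid", "diploid", "diploid",
#'                "subgenome", "subgenome", "outgroup"),
#'              subgenome_parent = c(At1 = "AD1", Dt1 = "AD1"))
#' @export
organism_set <- function(ids, roles, subgenome_parent = NULL, labels = NULL) {
  ids <- as.character(ids)
  roles <- as.character(roles)
  if (length(ids) != length(roles))
    stop("'ids' and 'roles' must have the same length")
  if (anyDuplicated(ids))
    stop("organism ids must be unique: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- setdiff(roles, c("diploid", "subgenome", "outgroup"))
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (sum(roles == "outgroup") > 1)
    stop("at most one outgroup organism is allowed")

  parent <- rep(NA_character_, length(ids))
  sub <- ids[roles == "subgenome"]
  if (length(sub)) {
    if (is.null(subgenome_parent))
      stop("'subgenome_parent' required when subgenome organisms are declared")
    missing_map <- setdiff(sub, names(subgenome_parent))
    if (length(missing_map))
      stop("subgenome(s) without a tetraploid mapping: ",
           paste(missing_map, collapse = ", "))
    parent[match(sub, ids)] <- as.character(subgenome_parent[sub])
    per_tet <- table(subgenome_parent[sub])
    if (any(per_tet != 2L))
      stop("every tetraploid must have exactly 2 subgenomes; violated for: ",
           paste(names(per_tet)[per_tet != 2L], collapse = ", "))
  }
  lab <- ids
  if (!is.null(labels)) lab[match(names(labels), ids)] <- as.character(labels)

  structure(
    data.frame(id = ids, role = roles, parent = parent, label = lab,
               stringsAsFactors = FALSE),
    class = c("organism_set", "data.frame"))
}

#' @export
print.organism_set <- function(x, ...) {
  cat("Organism set:", nrow(x), "organisms (",
      sum(x$role == "diploid"), "diploid,",
      sum(x$role == "subgenome"), "subgenome,",
      sum(x$role == "outgroup"), "outgroup )\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @rdname organism_set
#' @param x An `organism_set`.
#' @export
outgroup_id <- function(x) {
  stopifnot(inherits(x, "organism_set"))
  og <- x$id[x$role == "outgroup"]
  if (length(og)) og else NA_character_
}

#' @rdname organism_set
#' @export
diploid_ids <- function(x) {
  stopifnot(inherits(x, "organism_set"))
  x$id[x$role == "diploid"]
}

#' @rdname organism_set
#' @param tetraploid A tetraploid id.
#' @export
subgenome_ids <- function(x, tetraploid) {
  stopifnot(inherits(x, "organism_set"))
  out <- x$id[!is.na(x$parent) & x$parent == tetraploid]
  if (length(out) != 2L)
    stop("tetraploid '", tetraploid, "' does not have 2 subgenomes in this set")
  out
}

#' Build and validate a sample sheet
#'
#' Maps RNA-seq samples (TPM table columns) to organisms and replicate
#' indices. Each organism points at one TPM table file; the sample id names
#' the column holding that replicate.
#'
#' @param sample Character vector of sample ids (must match TPM table column
#'   names).
#' @param organism Character vector of organism ids.
#' @param replicate Integer replicate index, unique within organism.
#' @param path File path of the TPM table holding the sample's column.
#' @param organisms Optional `organism_set` to validate organism ids against.
#' @return A data frame of class `sample_sheet`.
#' @export
sample_sheet <- function(sample, organism, replicate, path, organisms = NULL) {
  df <- data.frame(sample = as.character(sample),
                   organism = as.character(organism),
                   replicate = as.integer(replicate),
                   path = as.character(path),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample))
    stop("sample ids must be unique")
  dup <- duplicated(df[c("organism", "replicate")])
  if (any(dup))
    stop("replicate indices must be unique within organism; duplicated: ",
         paste(df$sample[dup], collapse = ", "))
  if (!is.null(organisms)) {
    unknown <- setdiff(df$organism, organisms$id)
    if (length(unknown))
      stop("sample sheet references unknown organism(s): ",
           paste(unknown, collapse = ", "))
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet from a TSV file
#'
#' Expects columns `sample`, `organism`, `replicate`, `path`. Relative paths
#' are resolved against the directory of the sheet itself.
#'
#' @param path Path to the TSV sheet.
#' @param organisms Optional `organism_set` for validation.
#' @return A `sample_sheet`.
#' @export
read_sample_sheet <- function(path, organisms = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "organism", "replicate", "path")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  sample_sheet(df$sample, df$organism, df$replicate, df$path, organisms)
}
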