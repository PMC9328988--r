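#' Construct an item dataset
#'
#' Records of a discretized dataset are stored as an integer matrix with one
#' column per attribute plus a final class column, each cell holding the item
#' ID observed for that attribute (NA marks a missing value).  Exactly one
#' item per attribute is the invariant enforced at construction.
#'
#' @param records either an integer matrix (columns in schema attribute order,
#'   class last) or a list of integer item-ID vectors, one per record.
#' @param schema an [attribute_schema()].
#' @return an object of class `item_dataset` with elements `schema`, `items`
#'   (the matrix) and `missing` (logical, per record).
#' @export
item_dataset <- function(records, schema) {
  stopifnot(inherits(schema, "attribute_schema"))
  cols <- c(names(schema$attributes), ".class")
  if (is.list(records)) {
    mat <- matrix(NA_integer_, nrow = length(records), ncol = length(cols),
                  dimnames = list(NULL, cols))
    owner <- item_owner(schema)
    for (i in seq_along(records)) {
      mat[i, ] <- itemize_record(records[[i]], schema, owner,
                                 where = sprintf("record %d", i))
    }
    records <- mat
  } else {
    records <- as.matrix(records)
    storage.mode(records) <- "integer"
    if (ncol(records) != length(cols))
      stop(sprintf("record matrix must have %d columns (attributes + class)",
                   length(cols)))
    colnames(records) <- cols
    validate_items(records, schema)
  }
  structure(list(schema = schema, items = records,
                 missing = apply(is.na(records), 1L, any)),
            class = "item_dataset")
}

# map one record's item-ID set onto the attribute columns; duplicates within
# an attribute or unknown IDs fail loudly, absent attributes become NA
itemize_record <- function(ids, schema, owner, where = "record") {
  ids <- as.integer(ids)
  cols <- c(names(schema$attributes), ".class")
  out <- stats::setNames(rep(NA_integer_, length(cols)), cols)
  for (id in ids) {
    who <- owner[as.character(id)]
    if (is.na(who))
      stop(sprintf("%s: item %d is not in the schema", where, id))
    slot <- if (who == "<class>") ".class" else who
    if (!is.na(out[slot]))
      stop(sprintf("%s: two items for attribute '%s' (%d and %d)",
                   where, who, out[slot], id))
    out[slot] <- id
  }
  out
}

validate_items <- function(mat, schema) {
  for (j in seq_along(schema$attributes)) {
    bad <- !is.na(mat[, j]) & !(mat[, j] %in% schema$attributes[[j]])
    if (any(bad))
      stop(sprintf("column '%s' holds item IDs outside its schema block",
                   names(schema$attributes)[j]))
  }
  badc <- !is.na(mat[, ".class"]) & !(mat[, ".class"] %in% schema$class_items)
  if (any(badc)) stop("class column holds non-class item IDs")
  invisible(TRUE)
}

#' @export
print.item_dataset <- function(x, ...) {
  cat(sprintf("item_dataset: %d records, %d attributes + class, %d flagged missing\n",
              n_records(x), n_attributes(x$schema), sum(x$missing)))
  invisible(x)
}

#' Number of records in an item dataset
#' @param ds an `item_dataset`.
#' @export
n_records <- function(ds) nrow(ds$items)

# logical class vector: TRUE where class item is the positive class
class_is_positive <- function(ds) {
  ds$items[, ".class"] == ds$schema$class_positive
}

subset_records <- function(ds, idx) {
  item_dataset(ds$items[idx, , drop = FALSE], ds$schema)
}

#' Read a LUCS-KDD item-number (.num) file
#'
#' Each non-empty line is a whitespace-separated list of positive integer
#' item IDs forming one record.  Items are validated against the schema; a
#' record lacking an attribute's item is flagged as missing rather than
#' rejected, so files that keep incomplete records can still be screened
#' with [drop_missing()].
#'
#' @param path file path.
#' @param schema an [attribute_schema()]; defaults to [wbc_schema()].
#' @return an `item_dataset` preserving record order.
#' @export
read_num <- function(path, schema = wbc_schema()) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  owner <- item_owner(schema)
  cols <- c(names(schema$attributes), ".class")
  mat <- matrix(NA_integer_, nrow = sum(keep), ncol = length(cols),
                dimnames = list(NULL, cols))
  r <- 0L
  for (ln in which(keep)) {
    toks <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    ids <- suppressWarnings(as.integer(toks))
    if (any(is.na(ids)))
      stop(sprintf("%s: line %d: non-integer token '%s'",
                   path, ln, toks[which(is.na(ids))[1]]))
    r <- r + 1L
    mat[r, ] <- itemize_record(ids, schema, owner,
                               where = sprintf("%s: line %d", path, ln))
  }
  item_dataset(mat, schema)
}

#' Write an item dataset in .num format
#'
#' One record per line, item IDs in ascending order, missing cells omitted.
#' Reading the file back with the same schema round-trips the dataset.
#'
#' @param ds an `item_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_num <- function(ds, path) {
  lines <- apply(ds$items, 1L, function(r)
    paste(sort(r[!is.na(r)]), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a raw-valued CSV and discretize it against a schema
#'
#' The CSV must have a header naming every schema attribute plus one class
#' column (any remaining column; `class` by convention).  Raw attribute
#' values are mapped to bin item IDs through the schema's `bins` tables;
#' class labels through `class_labels`.  Cells that are empty or `?` are
#' treated as missing and flag the record.
#'
#' @param path CSV file path.
#' @param schema an [attribute_schema()] carrying `bins` and `class_labels`.
#' @param class_col name of the class column (default `"class"`).
#' @return an `item_dataset` with missing records flagged, not removed.
#' @export
read_csv_discretize <- function(path, schema = wbc_schema(),
                                class_col = "class") {
  if (is.null(schema$bins))
    stop("schema carries no raw-value bins; cannot discretize")
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", na.strings = c("?", ""))
  need <- c(names(schema$attributes), class_col)
  if (!all(need %in% names(df)))
    stop(sprintf("CSV is missing columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  cols <- c(names(schema$attributes), ".class")
  mat <- matrix(NA_integer_, nrow = nrow(df), ncol = length(cols),
                dimnames = list(NULL, cols))
  for (nm in names(schema$attributes)) {
    b <- schema$bins[[nm]]
    raw <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- !is.na(df[[nm]]) & is.na(raw)
    if (any(bad))
      stop(sprintf("column '%s': non-numeric value '%s'",
                   nm, df[[nm]][which(bad)[1]]))
    item <- rep(NA_integer_, nrow(df))
    for (k in seq_len(nrow(b)))
      item[!is.na(raw) & raw >= b$lo[k] & raw <= b$hi[k]] <- b$item[k]
    out_of_range <- !is.na(raw) & is.na(item)
    if (any(out_of_range))
      stop(sprintf("column '%s': value %s outside declared bins",
                   nm, raw[which(out_of_range)[1]]))
    mat[, nm] <- item
  }
  lab <- df[[class_col]]
  known <- is.na(lab) | lab %in% names(schema$class_labels)
  if (!all(known))
    stop(sprintf("unknown class label '%s'", lab[which(!known)[1]]))
  mat[, ".class"] <- ifelse(is.na(lab), NA_integer_,
                            schema$class_labels[lab])
  item_dataset(mat, schema)
}

#' Drop records flagged as missing
#'
#' Removes every record carrying a missing value and reports how many were
#' removed (attribute `n_removed` on the result, plus a message).
#'
#' @param ds an `item_dataset`.
#' @param quiet suppress the message.
#' @return the filtered `item_dataset`; `attr(, "n_removed")` holds the count.
#' @export
drop_missing <- function(ds, quiet = FALSE) {
  n_removed <- sum(ds$missing)
  out <- item_dataset(ds$items[!ds$missing, , drop = FALSE], ds$schema)
  attr(out, "n_removed") <- n_removed
  if (!quiet && n_removed > 0L)
    message(sprintf("dropped %d record(s) with missing values", n_removed))
  out
}
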