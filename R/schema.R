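#' Attribute schema for a discretized dataset
#'
#' A schema names the clinical attributes, assigns each discretized bin a
#' globally unique positive integer item ID (contiguous block per attribute),
#' and declares the class attribute: its two item IDs and which of them is
#' the positive ("yes", malignant) class.
#'
#' @param attributes named list; one element per attribute, each an integer
#'   vector of at least two item IDs (one per discretized bin), in bin order.
#' @param class_items integer vector of length two: the item IDs of the two
#'   class labels, negative ("no") first.
#' @param class_positive single item ID from `class_items` meaning class = yes.
#' @param bins optional named list parallel to `attributes`; each element a
#'   data.frame with columns `lo`, `hi`, `item` giving the raw-value range of
#'   each bin, used by [read_csv_discretize()].
#' @param class_labels optional character vector, names being the raw class
#'   labels accepted in CSV input and values the corresponding item IDs.
#' @return an object of class `attribute_schema`.
#' @seealso [wbc_schema()] for the default breast-cancer layout.
#' @export
attribute_schema <- function(attributes, class_items, class_positive,
                             bins = NULL, class_labels = NULL) {
  stopifnot(is.list(attributes), length(attributes) >= 1,
            !is.null(names(attributes)), all(nzchar(names(attributes))))
  attributes <- lapply(attributes, function(x) as.integer(x))
  class_items <- as.integer(class_items)
  class_positive <- as.integer(class_positive)
  if (length(class_items) != 2L)
    stop("exactly one class attribute with two item IDs is required")
  if (!class_positive %in% class_items)
    stop("class_positive must be one of class_items")
  all_ids <- c(unlist(attributes, use.names = FALSE), class_items)
  if (any(is.na(all_ids)) || any(all_ids <= 0L))
    stop("item IDs must be positive integers")
  if (anyDuplicated(all_ids))
    stop("item IDs must be globally unique")
  if (any(vapply(attributes, length, 1L) < 2L))
    stop("every attribute needs at least two bins")
  if (!is.null(bins)) {
    stopifnot(is.list(bins), setequal(names(bins), names(attributes)))
    bins <- bins[names(attributes)]
  }
  structure(
    list(attributes = attributes, class_items = class_items,
         class_positive = class_positive, bins = bins,
         class_labels = class_labels),
    class = "attribute_schema")
}

#' Default Wisconsin breast-cancer schema
#'
#' Nine cytology attributes, each measured on 1--10 and discretized into a
#' low (1--5) and a high (6--10) bin, followed by the binary class
#' (benign / malignant).  Item IDs run 1..20 in attribute order, the class
#' occupying 19 (benign) and 20 (malignant, the positive class).
#'
#' @return an `attribute_schema`.
#' @export
wbc_schema <- function() {
  nm <- c("clump_thickness", "uniformity_of_cell_size",
          "uniformity_of_cell_shape", "marginal_adhesion",
          "single_epithelial_cell_size", "bare_nuclei", "bland_chromatin",
          "normal_nucleoli", "mitoses")
  attrs <- stats::setNames(lapply(seq_along(nm), function(i) {
    as.integer(c(2L * i - 1L, 2L * i))
  }), nm)
  bins <- stats::setNames(lapply(seq_along(nm), function(i) {
    data.frame(lo = c(1, 6), hi = c(5, 10), item = c(2L * i - 1L, 2L * i))
  }), nm)
  attribute_schema(
    attrs, class_items = c(19L, 20L), class_positive = 20L, bins = bins,
    class_labels = c(benign = 19L, malignant = 20L, "2" = 19L, "4" = 20L))
}

#' @export
print.attribute_schema <- function(x, ...) {
  cat(sprintf("attribute_schema: %d attributes + class\n", length(x$attributes)))
  for (nm in names(x$attributes))
    cat(sprintf("  %-28s items %s\n", nm,
                paste(x$attributes[[nm]], collapse = ",")))
  cat(sprintf("  %-28s items %s (positive: %d)\n", "<class>",
              paste(x$class_items, collapse = ","), x$class_positive))
  invisible(x)
}

# item ID -> attribute name ("<class>" for class items)
item_owner <- function(schema) {
  ids <- c(unlist(schema$attributes, use.names = FALSE), schema$class_items)
  owner <- c(rep(names(schema$attributes),
                 vapply(schema$attributes, length, 1L)),
             rep("<class>", 2L))
  stats::setNames(owner, ids)
}

attribute_item_ids <- function(schema) {
  unlist(schema$attributes, use.names = FALSE)
}

n_attributes <- function(schema) length(schema$attributes)

#' Read / write a schema as YAML
#'
#' The YAML layout mirrors the constructor: an `attributes` map from name to
#' either an `items` list or a `bins` list of `{lo, hi, item}` entries, a
#' `class` block with `items`, `positive` and optional `labels`.
#'
#' @param path file path.
#' @return `read_schema_yaml` returns an `attribute_schema`;
#'   `write_schema_yaml` returns `path` invisibly.
#' @export
read_schema_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  attrs <- lapply(y$attributes, function(a) {
    if (!is.null(a$items)) as.integer(unlist(a$items))
    else as.integer(vapply(a$bins, function(b) b$item, 1))
  })
  bins <- NULL
  if (all(vapply(y$attributes, function(a) !is.null(a$bins), TRUE))) {
    bins <- lapply(y$attributes, function(a) {
      do.call(rbind, lapply(a$bins, function(b)
        data.frame(lo = b$lo, hi = b$hi, item = as.integer(b$item))))
    })
  }
  labels <- NULL
  if (!is.null(y$class$labels))
    labels <- stats::setNames(as.integer(unlist(y$class$labels)),
                              names(y$class$labels))
  attribute_schema(attrs,
                   class_items = as.integer(unlist(y$class$items)),
                   class_positive = as.integer(y$class$positive),
                   bins = bins, class_labels = labels)
}

#' @rdname read_schema_yaml
#' @param schema an `attribute_schema`.
#' @export
write_schema_yaml <- function(schema, path) {
  attrs <- lapply(names(schema$attributes), function(nm) {
    if (!is.null(schema$bins)) {
      b <- schema$bins[[nm]]
      list(bins = lapply(seq_len(nrow(b)), function(i)
        list(lo = b$lo[i], hi = b$hi[i], item = b$item[i])))
    } else {
      list(items = as.list(schema$attributes[[nm]]))
    }
  })
  names(attrs) <- names(schema$attributes)
  y <- list(attributes = attrs,
            class = list(items = as.list(schema$class_items),
                         positive = schema$class_positive))
  if (!is.null(schema$class_labels))
    y$class$labels <- as.list(schema$class_labels)
  yaml::write_yaml(y, path)
  invisible(path)
}
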