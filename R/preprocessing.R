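#' Fit the feature-encoding schema on training annotations
#'
#' The encoding contract is fitted once on the training set and then applied
#' unchanged to any later data, so train and test matrices always share the
#' same columns. Per categorical feature the (at most) five most frequent
#' levels are retained, ties broken lexicographically; per numerical feature
#' a fixed imputation value is recorded — an externally recommended value if
#' supplied via `imputation_overrides`, otherwise the training median.
#'
#' @param annotations training annotation tibble (see [read_annotations()]).
#' @param feature_names manifest as in [default_feature_names()].
#' @param imputation_overrides optional named numeric vector/list of
#'   imputation values keyed by numerical feature name.
#' @param max_levels number of categorical levels retained (default 5).
#' @param include_af whether the population allele frequency is appended as
#'   an additional model feature (default `TRUE`).
#' @param af_feature_name output column name for the AF feature.
#' @return a `feature_schema` object.
#' @export
fit_feature_schema <- function(annotations,
                               feature_names = default_feature_names(),
                               imputation_overrides = NULL,
                               max_levels = 5,
                               include_af = TRUE,
                               af_feature_name = "allele_frequency") {
  if (nrow(annotations) == 0) abort("cannot fit a feature schema on an empty training set")
  check_annotation_columns(annotations, feature_names)

  categorical_levels <- lapply(feature_names$categorical, function(nm) {
    x <- annotations[[nm]]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      inform(paste0("categorical feature '", nm,
                    "' entirely absent in training; zero levels retained"))
      return(character())
    }
    counts <- sort(table(x), decreasing = TRUE)
    # stable top-k: order by count desc then level name asc
    ord <- order(-as.integer(counts), names(counts))
    head(names(counts)[ord], max_levels)
  })
  names(categorical_levels) <- feature_names$categorical

  imputation_values <- vapply(feature_names$numerical, function(nm) {
    ov <- imputation_overrides[[nm]]
    if (!is.null(ov)) return(as.numeric(ov))
    x <- annotations[[nm]]
    v <- median(x, na.rm = TRUE)
    if (is.na(v)) 0 else v
  }, double(1))

  schema <- structure(
    list(categorical_levels = categorical_levels,
         imputation_values = as.list(imputation_values),
         feature_names = feature_names,
         include_af = include_af,
         af_feature_name = af_feature_name,
         version = as.character(utils::packageVersion("pathboost"))),
    class = "feature_schema")
  schema$feature_order <- compute_feature_order(schema)
  schema
}

compute_feature_order <- function(schema) {
  cat_cols <- unlist(lapply(names(schema$categorical_levels), function(nm) {
    c(paste0(nm, "_", schema$categorical_levels[[nm]]),
      paste0(nm, "_other"), paste0(nm, "_missing"))
  }), use.names = FALSE)
  c(cat_cols, schema$feature_names$numerical,
    if (schema$include_af) schema$af_feature_name)
}

check_annotation_columns <- function(annotations, feature_names) {
  declared <- c(feature_names$categorical, feature_names$numerical)
  missing <- setdiff(declared, names(annotations))
  extra <- setdiff(names(annotations), c("chrom", "pos", "ref", "alt", declared))
  if (length(missing) > 0 || length(extra) > 0) {
    abort(paste0(
      "annotations do not match the feature schema",
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
      if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", "))
    ))
  }
  invisible(TRUE)
}

#' @export
print.feature_schema <- function(x, ...) {
  n_cat <- length(x$categorical_levels)
  n_num <- length(x$imputation_values)
  cat("<feature_schema> ", n_cat, " categorical + ", n_num, " numerical",
      if (x$include_af) " + allele frequency", "; ",
      length(x$feature_order), " encoded columns\n", sep = "")
  invisible(x)
}

#' Encode annotations into a dense model matrix
#'
#' Applies a fitted schema: each categorical feature expands to one 0/1
#' indicator per retained level plus an `_other` indicator (observed but
#' unretained level) and a `_missing` indicator (absent value); numerical
#' features pass through with absent values replaced by the schema's
#' imputation value; the population allele frequency is appended from the
#' lookup, defaulting to 0 for variants absent from it. The result contains
#' no missing values and its columns always equal `schema$feature_order`,
#' regardless of what the input happened to contain.
#'
#' @param annotations annotation tibble.
#' @param schema a fitted [fit_feature_schema()] object.
#' @param af_lookup optional tibble `chrom,pos,ref,alt,af` (gnomAD-style);
#'   ignored when the schema excludes the AF feature.
#' @return a tibble: key columns `chrom,pos,ref,alt` followed by the encoded
#'   feature columns in schema order, with the schema attached as attribute
#'   `"schema"`.
#' @export
encode_features <- function(annotations, schema, af_lookup = NULL) {
  stopifnot(inherits(schema, "feature_schema"))
  check_annotation_columns(annotations, schema$feature_names)
  n <- nrow(annotations)

  blocks <- lapply(names(schema$categorical_levels), function(nm) {
    levels <- schema$categorical_levels[[nm]]
    x <- annotations[[nm]]
    m <- matrix(0, nrow = n, ncol = length(levels) + 2,
                dimnames = list(NULL, c(paste0(nm, "_", levels),
                                        paste0(nm, "_other"),
                                        paste0(nm, "_missing"))))
    for (j in seq_along(levels)) m[, j] <- as.numeric(!is.na(x) & x == levels[j])
    m[, length(levels) + 1] <- as.numeric(!is.na(x) & !x %in% levels)
    m[, length(levels) + 2] <- as.numeric(is.na(x))
    m
  })

  num <- vapply(schema$feature_names$numerical, function(nm) {
    x <- annotations[[nm]]
    x[is.na(x)] <- schema$imputation_values[[nm]]
    x
  }, double(n))
  if (n == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, schema$feature_names$numerical))

  out <- cbind(do.call(cbind, blocks), num)
  if (schema$include_af) {
    af <- rep(0, n)
    if (!is.null(af_lookup) && nrow(af_lookup) > 0) {
      hit <- match(variant_key(annotations), variant_key(af_lookup))
      af[!is.na(hit)] <- af_lookup$af[hit[!is.na(hit)]]
    }
    out <- cbind(out, matrix(af, ncol = 1,
                             dimnames = list(NULL, schema$af_feature_name)))
  }
  out <- out[, schema$feature_order, drop = FALSE]

  res <- bind_cols(annotations[c("chrom", "pos", "ref", "alt")], as_tibble(out))
  attr(res, "schema") <- schema
  res
}

#' Encoded feature column names of a schema
#'
#' @param schema a `feature_schema`.
#' @return character vector of model-matrix column names, in order.
#' @export
feature_columns <- function(schema) schema$feature_order

# pull the numeric model matrix out of an encoded tibble, in schema order
encoded_matrix <- function(encoded, schema) {
  cols <- feature_columns(schema)
  missing <- setdiff(cols, names(encoded))
  if (length(missing) > 0) {
    abort(paste0("encoded matrix is missing schema column(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  as.matrix(encoded[cols])
}

#' Serialize / restore a feature schema as JSON
#'
#' The schema is the train-time contract that must travel with any trained
#' model; JSON keeps it inspectable and diffable.
#'
#' @param schema a `feature_schema`.
#' @param path JSON file path.
#' @return `read_feature_schema()` returns the restored `feature_schema`;
#'   column order is preserved exactly across the round trip.
#' @export
write_feature_schema <- function(schema, path) {
  jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_schema
#' @export
read_feature_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$categorical_levels <- lapply(raw$categorical_levels, as.character)
  raw$imputation_values <- lapply(raw$imputation_values, as.numeric)
  raw$feature_names <- lapply(raw$feature_names, as.character)
  raw$feature_order <- as.character(raw$feature_order)
  structure(raw, class = "feature_schema")
}
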