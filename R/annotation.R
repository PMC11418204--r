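#' @title B vitamin enzyme annotation
#' @description Data model and loader for the enzyme-to-(vitamin, role)
#'   annotation that drives the synthesis/downstream (S/D) analysis. Roles:
#'   `S` = synthesis/upstream, `D` = downstream utilization, `T` = transport.
#'   Classification follows the colonically absorbed form of each vitamin:
#'   the kinase producing thiamine pyrophosphate (TPP, the form taken up by
#'   the colonic TPP transporter) is upstream (`S`), and bacterial
#'   pantothenate/pyridoxal kinases are likewise upstream because host
#'   enzymes readily dephosphorylate those compounds in the lumen.
#' @name annotation
NULL

VITAMIN_CODES <- c("B1", "B2", "B3", "B5", "B6", "B7", "B9", "B12")
ROLE_CODES <- c("S", "D", "T")

# EC identifier: "EC " then four dot-separated fields, digits or dashes
is_valid_ec <- function(x) {
  grepl("^EC [0-9]+(\\.([0-9]+|-)){3}$", x)
}

new_vitamin_annotation <- function(records) {
  stopifnot(is.data.frame(records))
  structure(records,
            vitamins_covered = sort(unique(records$vitamin)),
            class = c("vitamin_annotation", "data.frame"))
}

validate_annotation <- function(df, origin = "annotation") {
  req <- c("feature_id", "vitamin", "role", "note")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(origin, ": missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(!nzchar(df$feature_id)))
      stop(origin, ": empty feature_id at line(s) ",
           paste(which(!nzchar(df$feature_id)), collapse = ", "))
    bad_v <- !(df$vitamin %in% VITAMIN_CODES)
    if (any(bad_v))
      stop(origin, ": unknown vitamin code(s) at line(s) ",
           paste(which(bad_v), collapse = ", "), ": ",
           paste(unique(df$vitamin[bad_v]), collapse = ", "))
    bad_r <- !(df$role %in% ROLE_CODES)
    if (any(bad_r))
      stop(origin, ": unknown role code(s) at line(s) ",
           paste(which(bad_r), collapse = ", "), ": ",
           paste(unique(df$role[bad_r]), collapse = ", "))
    is_ec <- startsWith(df$feature_id, "EC ")
    bad_ec <- is_ec & !is_valid_ec(df$feature_id)
    if (any(bad_ec))
      stop(origin, ": malformed EC identifier at line(s) ",
           paste(which(bad_ec), collapse = ", "), ": ",
           paste(df$feature_id[bad_ec], collapse = ", "))
    key <- paste(df$feature_id, df$vitamin)
    dup <- duplicated(key)
    if (any(dup))
      stop(origin, ": duplicate (feature_id, vitamin) pair(s) at line(s) ",
           paste(which(key %in% key[dup]), collapse = ", "))
  }
  df
}

#' Load a vitamin annotation table
#'
#' Reads a tab-separated annotation with header columns
#' `feature_id`, `vitamin`, `role`, `note`. Vitamin codes are
#' B1, B2, B3, B5, B6, B7, B9, B12; role codes are S (synthesis/upstream),
#' D (downstream utilization), T (transport). Feature IDs beginning with
#' `"EC "` are syntactically checked (four dot-separated fields, dashes
#' allowed); duplicate `(feature_id, vitamin)` pairs and unknown codes are
#' rejected with line numbers.
#'
#' @param path Path to an annotation TSV.
#' @return A `vitamin_annotation` data frame with attribute
#'   `vitamins_covered`.
#' @seealso [builtin_demo_annotation()], [write_annotation()]
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          check.names = FALSE)
  df <- validate_annotation(df, origin = basename(path))
  new_vitamin_annotation(df)
}

#' Write a vitamin annotation table
#'
#' Serialises a `vitamin_annotation` to the TSV dialect read by
#' [load_annotation()] (round-trip safe).
#'
#' @param ann A `vitamin_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "vitamin_annotation"))
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bundled demonstration annotation
#'
#' A small synthetic annotation fixture covering all 8 B vitamins with at
#' least one synthesis (S) and one downstream-utilization (D) enzyme each,
#' plus transporters (T). It encodes the colonic-form classification rules:
#' thiamine diphosphokinase (produces TPP) is upstream for B1, and the
#' bacterial pantothenate and pyridoxal kinases are upstream for B5/B6.
#' It is a demonstration stand-in for a full manual pathway annotation,
#' which users supply via [load_annotation()].
#'
#' @return A `vitamin_annotation`.
#' @export
builtin_demo_annotation <- function() {
  path <- system.file("extdata", "demo_vitamin_annotation.tsv",
                      package = "vitaminSD", mustWork = TRUE)
  load_annotation(path)
}

#' @export
print.vitamin_annotation <- function(x, ...) {
  cat("Vitamin annotation:", nrow(x), "records;",
      length(attr(x, "vitamins_covered")), "vitamins covered\n")
  NextMethod()
}
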