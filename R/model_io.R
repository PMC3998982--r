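#' Read and write food web model bundles
#'
#' A model bundle is either a directory containing `groups.csv`, `diet.csv`
#' and optionally `metadata.json`, or a single `.json` file mirroring the
#' same fields. `groups.csv` has columns `name, role, producer_fraction, B,
#' PB, QB, EE, GS, Y, E, BA, import_diet`; `diet.csv` is the square diet
#' matrix with prey as rows and predators as columns, labelled by group
#' name. Round-tripping through either format is lossless to numerical
#' precision.
#'
#' @param path Bundle directory or `.json` file ([load_model()]); target
#'   directory or `.json` path ([save_model()]).
#' @param m A `food_web_model`.
#' @param format `"dir"` (CSV bundle) or `"json"`; for [save_model()]
#'   inferred from a `.json` extension when not given.
#' @return [load_model()] returns a validated `food_web_model`;
#'   [save_model()] returns `path` invisibly.
#' @export
load_model <- function(path) {
  if (dir.exists(path)) {
    gfile <- file.path(path, "groups.csv")
    dfile <- file.path(path, "diet.csv")
    if (!file.exists(gfile)) stop("bundle is missing groups.csv: ", path)
    if (!file.exists(dfile)) stop("bundle is missing diet.csv: ", path)
    groups <- utils::read.csv(gfile, stringsAsFactors = FALSE)
    diet <- as.matrix(utils::read.csv(dfile, row.names = 1, check.names = FALSE))
    meta <- list(name = basename(path), area = NA_real_, year = NA_integer_)
    mfile <- file.path(path, "metadata.json")
    if (file.exists(mfile)) {
      meta <- utils::modifyList(meta, jsonlite::read_json(mfile, simplifyVector = TRUE))
    }
  } else if (file.exists(path) && grepl("\\.json$", path)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (fld in c("groups", "diet")) {
      if (is.null(raw[[fld]])) stop("model JSON is missing field: ", fld)
    }
    groups <- as.data.frame(raw$groups, stringsAsFactors = FALSE)
    diet <- as.matrix(raw$diet)
    meta <- utils::modifyList(
      list(name = sub("\\.json$", "", basename(path)),
           area = NA_real_, year = NA_integer_),
      as.list(raw$metadata)
    )
  } else {
    stop("no model bundle at ", path)
  }
  required <- c("name", "role", "B", "PB")
  missing_cols <- setdiff(required, names(groups))
  if (length(missing_cols)) {
    stop("model bundle is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(dim(diet) == nrow(groups))) {
    stop("diet matrix dimensions do not match the number of groups")
  }
  if (!is.null(rownames(diet)) && !identical(rownames(diet), as.character(groups$name))) {
    diet <- diet[as.character(groups$name), , drop = FALSE]
  }
  if (!is.null(colnames(diet)) && !identical(colnames(diet), as.character(groups$name))) {
    diet <- diet[, as.character(groups$name), drop = FALSE]
  }
  food_web_model(groups, diet, name = meta$name, area = meta$area, year = meta$year)
}

#' @rdname load_model
#' @export
save_model <- function(m, path, format = c("auto", "dir", "json")) {
  stopifnot(inherits(m, "food_web_model"))
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.json$", path)) "json" else "dir"
  if (format == "json") {
    jsonlite::write_json(
      list(groups = m$groups,
           diet = m$diet,
           metadata = m$meta),
      path, digits = NA, auto_unbox = TRUE, na = "null", matrix = "rowmajor"
    )
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(m$groups, file.path(path, "groups.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(m$diet), file.path(path, "diet.csv"))
    jsonlite::write_json(m$meta, file.path(path, "metadata.json"),
                         digits = NA, auto_unbox = TRUE, na = "null")
  }
  invisible(path)
}
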