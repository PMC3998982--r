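#' Construct a mass-balanced food web model
#'
#' A `food_web_model` is the unit of analysis: an ordered set of functional
#' groups (producers, consumers, detritus pools) with Ecopath-style biological
#' parameters, a diet composition matrix, and fisheries removals.
#'
#' @param groups A data frame with one row per functional group. Required
#'   columns: `name`, `role` (one of `"producer"`, `"consumer"`,
#'   `"detritus"`), `B` (biomass, t km-2), `PB` (production/biomass, y-1).
#'   `QB` (consumption/biomass, y-1) is required for consumers. Optional
#'   columns with defaults: `producer_fraction` (1 for producers, 0
#'   otherwise; values in (0,1) mark mixed producer/consumers), `EE`
#'   (ecotrophic efficiency, estimated if `NA`), `GS` (unassimilated
#'   fraction of consumption, default 0.2), `Y` (fisheries removals,
#'   t km-2 y-1, default 0), `E` (non-fishery export, default 0), `BA`
#'   (biomass accumulation, default 0), `import_diet` (fraction of diet
#'   imported, default 0).
#' @param diet Square numeric matrix, `diet[i, j]` = proportion of prey `i`
#'   in the diet of predator `j`. Row and column order must match `groups`.
#' @param name,area,year Optional metadata.
#' @param validate Run [validate_model()] on the result (default `TRUE`).
#'
#' @return An object of class `food_web_model`: a list with elements
#'   `groups` (completed data frame), `diet` (named matrix) and `meta`.
#' @seealso [load_model()], [estimate_ee()], [build_flows()]
#' @export
#' @examples
#' m <- fixture_chain3()
#' m$groups[, c("name", "role", "B", "PB")]
food_web_model <- function(groups, diet, name = "model", area = NA_real_,
                           year = NA_integer_, validate = TRUE) {
  stopifnot(is.data.frame(groups))
  required <- c("name", "role", "B", "PB")
  missing_cols <- setdiff(required, names(groups))
  if (length(missing_cols)) {
    stop("missing required group column(s): ", paste(missing_cols, collapse = ", "))
  }
  groups$name <- as.character(groups$name)
  groups$role <- as.character(groups$role)
  if (!all(groups$role %in% c("producer", "consumer", "detritus"))) {
    stop("role must be one of 'producer', 'consumer', 'detritus'")
  }
  n <- nrow(groups)
  defaults <- list(
    producer_fraction = ifelse(groups$role == "producer", 1, 0),
    QB = NA_real_, EE = NA_real_, GS = 0.2, Y = 0, E = 0, BA = 0,
    import_diet = 0
  )
  for (col in names(defaults)) {
    def <- rep_len(defaults[[col]], n)
    if (is.null(groups[[col]])) {
      groups[[col]] <- def
    } else if (!col %in% c("QB", "EE")) {
      idx <- is.na(groups[[col]])
      groups[[col]][idx] <- def[idx]
    }
  }
  groups <- groups[, c("name", "role", "producer_fraction", "B", "PB", "QB",
                       "EE", "GS", "Y", "E", "BA", "import_diet")]
  diet <- as.matrix(diet)
  if (!all(dim(diet) == n)) stop("diet matrix must be ", n, " x ", n)
  dimnames(diet) <- list(groups$name, groups$name)
  m <- structure(
    list(groups = groups, diet = diet,
         meta = list(name = name, area = area, year = year)),
    class = "food_web_model"
  )
  if (validate) validate_model(m)
  m
}

#' Validate a food web model
#'
#' Checks the structural invariants: nonnegative biomasses and rates,
#' diet proportions in \[0, 1\], diet columns of consumers summing to
#' 1 - import fraction (absolute tolerance 1e-6), all-zero diet columns for
#' pure producers and detritus, and presence of at least one producer or
#' detritus group.
#'
#' @param m A `food_web_model`.
#' @param renormalize If `TRUE`, diet columns whose sums are off are rescaled
#'   to satisfy the constraint instead of raising an error. Never silent:
#'   a message reports every renormalized predator.
#' @param tol Absolute tolerance on diet column sums (default 1e-6).
#' @return The (possibly renormalized) model, invisibly for the default path.
#' @export
validate_model <- function(m, renormalize = FALSE, tol = 1e-6) {
  stopifnot(inherits(m, "food_web_model"))
  g <- m$groups
  if (anyDuplicated(g$name)) stop("duplicate group names")
  if (any(g$B < 0, na.rm = TRUE)) stop("negative biomass")
  if (any(g$PB < 0, na.rm = TRUE)) stop("negative PB")
  if (any(g$QB < 0, na.rm = TRUE)) stop("negative QB")
  if (any(g$GS < 0 | g$GS >= 1)) stop("GS must lie in [0, 1)")
  if (any(g$producer_fraction < 0 | g$producer_fraction > 1)) {
    stop("producer_fraction must lie in [0, 1]")
  }
  if (!any(g$role %in% c("producer", "detritus"))) {
    stop("model needs at least one producer or detritus group")
  }
  consumer <- is_consumer(m)
  if (any(consumer & is.na(g$QB))) {
    stop("missing required column value: QB for consumer(s) ",
         paste(g$name[consumer & is.na(g$QB)], collapse = ", "))
  }
  d <- m$diet
  if (any(d < -tol) || any(d > 1 + tol)) stop("diet entries must lie in [0, 1]")
  nondiet <- !consumer
  if (any(d[, nondiet, drop = FALSE] != 0)) {
    stop("producers and detritus must have all-zero diet columns: ",
         paste(g$name[nondiet][colSums(d[, nondiet, drop = FALSE] != 0) > 0],
               collapse = ", "))
  }
  sums <- colSums(d) + g$import_diet
  bad <- consumer & abs(sums - 1) > tol
  if (any(bad)) {
    if (renormalize) {
      for (j in which(bad)) {
        message("renormalizing diet column of ", g$name[j],
                " (sum was ", format(sums[j]), ")")
        m$diet[, j] <- m$diet[, j] * (1 - g$import_diet[j]) / sum(m$diet[, j])
      }
    } else {
      stop("diet column sum violation for predator(s): ",
           paste(sprintf("%s (%.6f)", g$name[bad], sums[bad]), collapse = ", "))
    }
  }
  invisible(m)
}

#' @export
print.food_web_model <- function(x, ...) {
  g <- x$groups
  cat("Food web model:", x$meta$name, "\n")
  cat(sprintf("  %d groups (%d producers, %d consumers, %d detritus), %d trophic links\n",
              nrow(g), sum(g$role == "producer"), sum(g$role == "consumer"),
              sum(g$role == "detritus"), sum(x$diet > 0)))
  cat(sprintf("  total biomass %.4g t km-2, total catch %.4g t km-2 y-1\n",
              sum(g$B), sum(g$Y)))
  invisible(x)
}

# role helpers -------------------------------------------------------------

is_living <- function(m) m$groups$role != "detritus"
is_detritus <- function(m) m$groups$role == "detritus"
is_producer <- function(m) m$groups$role == "producer" | m$groups$producer_fraction >= 1
is_consumer <- function(m) {
  m$groups$role == "consumer" & m$groups$producer_fraction < 1
}

#' Consumption, production and primary production vectors
#'
#' `consumption()` returns realized food intake per group,
#' Q = B * QB * (1 - producer_fraction) (zero for pure producers and
#' detritus); `production()` returns B * PB; `primary_production()` returns
#' the autotrophic part producer_fraction * B * PB.
#'
#' @param m A `food_web_model`.
#' @return Named numeric vector, t km-2 y-1.
#' @export
consumption <- function(m) {
  g <- m$groups
  q <- ifelse(is_consumer(m), g$B * g$QB * (1 - g$producer_fraction), 0)
  q[is.na(q)] <- 0
  stats::setNames(q, g$name)
}

#' @rdname consumption
#' @export
production <- function(m) {
  stats::setNames(ifelse(is_detritus(m), 0, m$groups$B * m$groups$PB),
                  m$groups$name)
}

#' @rdname consumption
#' @export
primary_production <- function(m) {
  stats::setNames(m$groups$producer_fraction * production(m), m$groups$name)
}

# predation flow matrix: flow[i, j] = consumption of prey i by predator j
predation_flows <- function(m) {
  q <- consumption(m)
  sweep(m$diet, 2, q, `*`)
}
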