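#' Define a DCE attribute
#'
#' An attribute is a treatment characteristic (e.g. overall response rate)
#' with a fixed, ordered set of levels, one of which is the reference level
#' against which part-worth utilities are expressed. Ordered attributes carry
#' a preference direction used to construct dominance-test tasks; benefit and
#' risk attributes on a numeric scale additionally carry per-level numeric
#' values so that trade-offs can be expressed in natural units (percentage
#' points, months).
#'
#' @param name Short machine identifier (used in column names).
#' @param label Display text.
#' @param kind One of `"benefit"`, `"risk"` or `"administration"`; the
#'   attribute group used when randomising presentation order.
#' @param levels Character vector of level labels, in presentation order
#'   (at least two, unique).
#' @param reference_index Position of the reference level in `levels`.
#' @param numeric_values Optional numeric value per level on a stated scale
#'   (percent or months); must be strictly monotone when given.
#' @param direction Preference direction over the level order: `1` if later
#'   levels are preferred (benefits listed worst to best), `-1` if earlier
#'   levels are preferred (risks listed best to worst), `0` if unordered
#'   (administration modes).
#' @return An object of class `dce_attribute`. Its `scale_width` field is
#'   `max(numeric_values) - min(numeric_values)` when numeric values are
#'   present, `NA` otherwise.
#' @export
attribute_spec <- function(name, label, kind = c("benefit", "risk", "administration"),
                           levels, reference_index = 1L, numeric_values = NULL,
                           direction = 0L) {
  kind <- match.arg(kind)
  levels <- as.character(levels)
  if (length(levels) < 2L) {
    stop("attribute '", name, "' needs at least 2 levels", call. = FALSE)
  }
  if (anyDuplicated(levels)) {
    stop("attribute '", name, "' has duplicated level labels", call. = FALSE)
  }
  reference_index <- as.integer(reference_index)
  if (reference_index < 1L || reference_index > length(levels)) {
    stop("reference_index out of range for attribute '", name, "'", call. = FALSE)
  }
  if (!is.null(numeric_values)) {
    if (length(numeric_values) != length(levels)) {
      stop("numeric_values must match the number of levels", call. = FALSE)
    }
    d <- diff(numeric_values)
    if (!(all(d > 0) || all(d < 0))) {
      stop("numeric_values must be strictly monotone", call. = FALSE)
    }
  }
  if (!direction %in% c(-1L, 0L, 1L)) {
    stop("direction must be -1, 0 or 1", call. = FALSE)
  }
  structure(
    list(
      name = name, label = label, kind = kind, levels = levels,
      reference_index = reference_index,
      numeric_values = if (is.null(numeric_values)) NULL else as.numeric(numeric_values),
      scale_width = if (is.null(numeric_values)) NA_real_ else diff(range(numeric_values)),
      direction = as.integer(direction)
    ),
    class = "dce_attribute"
  )
}

#' @export
print.dce_attribute <- function(x, ...) {
  ref <- x$levels[x$reference_index]
  cat(sprintf("<dce_attribute> %s (%s): %s [ref: %s]\n",
              x$name, x$kind, paste(x$levels, collapse = " / "), ref))
  invisible(x)
}

#' Default attribute catalog for the RRMM treatment-preference DCE
#'
#' The eight attributes used in the relapsed/refractory multiple myeloma
#' benefit-risk study: three benefits (overall response rate, duration of
#' response, overall survival), four risks (peripheral neuropathy, temporary
#' vision change, cytokine release syndrome, severe diarrhea) and the mode of
#' administration (five modes, from frequent IV/SC dosing to the one-time
#' CAR-T procedure bundle).
#'
#' Reference levels are the lowest benefit, the no-risk level of each risk,
#' and IV/SC administration every 3 weeks (the comparator used for the
#' administration trade-off). The catalog has 31 levels in total, hence 23
#' non-reference part-worth coefficients.
#'
#' @return A list of [attribute_spec()] objects of class `dce_catalog`.
#' @examples
#' cat8 <- default_catalog()
#' sapply(cat8, function(a) length(a$levels))
#' @export
default_catalog <- function() {
  structure(list(
    attribute_spec(
      "orr", "Likelihood of responding to treatment (ORR)", "benefit",
      levels = c("25", "40", "55", "70", "85"),
      reference_index = 1L, numeric_values = c(25, 40, 55, 70, 85), direction = 1L
    ),
    attribute_spec(
      "dor", "Length of time in response (DOR)", "benefit",
      levels = c("3mo", "6mo", "9mo", "12mo", "15mo"),
      reference_index = 1L, numeric_values = c(3, 6, 9, 12, 15), direction = 1L
    ),
    attribute_spec(
      "os", "Lifespan (OS)", "benefit",
      levels = c("6mo", "12mo", "18mo", "24mo"),
      reference_index = 1L, numeric_values = c(6, 12, 18, 24), direction = 1L
    ),
    attribute_spec(
      "neuropathy", "Tingling or pain in hands/feet (peripheral neuropathy)", "risk",
      levels = c("0", "25", "50"),
      reference_index = 1L, numeric_values = c(0, 25, 50), direction = -1L
    ),
    attribute_spec(
      "ocular", "Temporary vision change", "risk",
      levels = c("0", "20", "40", "60"),
      reference_index = 1L, numeric_values = c(0, 20, 40, 60), direction = -1L
    ),
    attribute_spec(
      "crs", "Inflammatory response (CRS)", "risk",
      levels = c("none", "high"),
      reference_index = 1L, direction = -1L
    ),
    attribute_spec(
      "diarrhea", "Severe diarrhea", "risk",
      levels = c("0", "10", "20"),
      reference_index = 1L, numeric_values = c(0, 10, 20), direction = -1L
    ),
    attribute_spec(
      "admin", "Administration", "administration",
      levels = c("ivsc_twice_weekly", "ivsc_q3w", "ivsc_weekly_pills",
                 "ivsc_monthly_pills", "cart_once"),
      reference_index = 2L, direction = 0L
    )
  ), class = "dce_catalog")
}

#' @export
print.dce_catalog <- function(x, ...) {
  cat(sprintf("<dce_catalog> %d attributes, %d levels, %d non-reference coefficients\n",
              length(x), sum(vapply(x, function(a) length(a$levels), 1L)),
              n_coefficients(x)))
  for (a in x) print(a)
  invisible(x)
}

as_catalog <- function(x) {
  if (!inherits(x, "dce_catalog")) {
    stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "dce_attribute")))
    class(x) <- "dce_catalog"
  }
  x
}

catalog_names <- function(catalog) vapply(catalog, `[[`, "", "name")

catalog_attribute <- function(catalog, name) {
  i <- match(name, catalog_names(catalog))
  if (is.na(i)) stop("unknown attribute '", name, "'", call. = FALSE)
  catalog[[i]]
}

#' Number of part-worth coefficients implied by a catalog
#'
#' One coefficient per non-reference level: `sum(levels - 1)` over attributes
#' (23 for [default_catalog()]).
#'
#' @param catalog A `dce_catalog`.
#' @return Integer count.
#' @export
n_coefficients <- function(catalog) {
  sum(vapply(catalog, function(a) length(a$levels) - 1L, 1L))
}

#' Coefficient names for the non-reference levels of a catalog
#'
#' Stable column order: attributes in catalog order, levels in level order
#' with the reference level dropped. Names have the form `attribute:level`.
#'
#' @param catalog A `dce_catalog`.
#' @return Character vector of length [n_coefficients()].
#' @export
coefficient_names <- function(catalog) {
  unlist(lapply(catalog, function(a) {
    paste0(a$name, ":", a$levels[-a$reference_index])
  }), use.names = FALSE)
}

# Per-attribute utility vector over all levels (reference = 0) from a named
# part-worth vector. Returns a named numeric over the attribute's levels.
attribute_utilities <- function(beta, attr) {
  u <- numeric(length(attr$levels))
  names(u) <- attr$levels
  nm <- paste0(attr$name, ":", attr$levels[-attr$reference_index])
  missing <- setdiff(nm, names(beta))
  if (length(missing) > 0) {
    stop("part-worth vector lacks coefficients: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  u[-attr$reference_index] <- beta[nm]
  u
}

#' Randomise attribute presentation order
#'
#' Attribute groups (benefit, risk, administration) are placed in uniformly
#' random order, and attributes are shuffled uniformly within each group, so
#' that attributes of a group always appear contiguously. Deterministic for a
#' given seed.
#'
#' @param catalog A `dce_catalog`.
#' @param seed Integer seed.
#' @return Character vector of attribute names in display order.
#' @export
presentation_order <- function(catalog, seed = 1L) {
  catalog <- as_catalog(catalog)
  kinds <- vapply(catalog, `[[`, "", "kind")
  nms <- catalog_names(catalog)
  with_seed(seed, {
    groups <- sample(unique(kinds))
    unlist(lapply(groups, function(g) sample(nms[kinds == g])), use.names = FALSE)
  })
}

#' Write or read an attribute catalog as a declarative YAML file
#'
#' @param catalog A `dce_catalog`.
#' @param path File path.
#' @return `read_catalog()` returns a `dce_catalog`; `write_catalog()`
#'   returns `path` invisibly.
#' @export
write_catalog <- function(catalog, path) {
  catalog <- as_catalog(catalog)
  out <- lapply(catalog, function(a) {
    x <- list(
      name = a$name, label = a$label, kind = a$kind,
      levels = as.list(a$levels),
      reference_index = a$reference_index,
      direction = a$direction
    )
    if (!is.null(a$numeric_values)) x$numeric_values <- as.list(a$numeric_values)
    x
  })
  yaml::write_yaml(list(attributes = out), path)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$attributes)) stop("not a catalog file: ", path, call. = FALSE)
  as_catalog(lapply(raw$attributes, function(a) {
    attribute_spec(
      name = a$name, label = a$label, kind = a$kind,
      levels = unlist(a$levels), reference_index = a$reference_index,
      numeric_values = if (is.null(a$numeric_values)) NULL else unlist(a$numeric_values),
      direction = a$direction
    )
  }))
}
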