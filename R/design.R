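# Master ordering of moderator terms; specs are stored in this order.
.term_order <- c(
  "intercept", "distance", "distance2", "diet", "bm", "habitat", "infratype",
  "distance:diet", "distance2:diet", "distance:bm", "distance2:bm",
  "distance:habitat", "distance2:habitat"
)

.main_of <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

#' Distance transform used by the meta-regressions
#'
#' Distance to infrastructure enters the models as `log10` metres.
#' Distances below 1 m (including 0 m records, which do occur in field
#' data) are clamped to 1 m so the transform is 0 at the infrastructure
#' edge and model intercepts are directly interpretable as the effect
#' "at 1 m".
#'
#' @param d_m distance in metres, `>= 0` (vectorised).
#' @return `log10(max(d_m, 1))`.
#' @export
transform_distance <- function(d_m) {
  if (any(is.na(d_m)) || any(d_m < 0)) stop("distance must be >= 0")
  log10(pmax(d_m, 1))
}

#' Construct a moderator specification
#'
#' A moderator spec is an ordered set of fixed-effect terms from the menu
#' `intercept, distance, distance2, diet, bm, habitat, infratype,
#' distance:diet, distance2:diet, distance:bm, distance2:bm,
#' distance:habitat, distance2:habitat`. Marginality is enforced: an
#' interaction requires both its main effects, `distance2` requires
#' `distance`, and `distance2:Z` requires `distance:Z`. Reference levels
#' are `habitat = closed` and `infratype = non_traffic`.
#'
#' @param terms character vector of term names; the intercept is always
#'   included and need not be listed.
#' @return object of class `moderator_spec`.
#' @export
moderator_spec <- function(terms = character(0)) {
  terms <- union("intercept", terms)
  bad <- setdiff(terms, .term_order)
  if (length(bad) > 0L)
    stop("unknown term(s): ", paste(bad, collapse = ", "))
  terms <- .term_order[.term_order %in% terms]
  # marginality
  for (tm in terms) {
    parts <- .main_of(tm)
    if (length(parts) == 2L) {
      if (!all(parts %in% terms))
        stop(sprintf("interaction '%s' requires main effect(s) %s", tm,
                     paste(setdiff(parts, terms), collapse = ", ")))
      if (parts[1] == "distance2") {
        lin <- paste0("distance:", parts[2])
        if (!(lin %in% terms))
          stop(sprintf("'%s' requires '%s'", tm, lin))
      }
    }
    if (tm == "distance2" && !("distance" %in% terms))
      stop("'distance2' requires 'distance'")
  }
  structure(list(terms = terms), class = "moderator_spec")
}

#' @export
print.moderator_spec <- function(x, ...) {
  cat("Moderator spec:", paste(x$terms, collapse = " + "), "\n")
  invisible(x)
}

#' @export
format.moderator_spec <- function(x, ...) paste(x$terms, collapse = "+")

.infra_levels_for <- function(taxon_group) {
  if (identical(taxon_group, "bird")) {
    c("non_traffic", "paved_road", "power_line", "unpaved_road")
  } else {
    c("non_traffic", "paved_road", "unpaved_road")
  }
}

# Expand one term into design columns for given moderder values.
.term_columns <- function(term, x, dist_x, taxon_group) {
  infra_levels <- .infra_levels_for(taxon_group)
  base <- switch(term,
    intercept = matrix(1, nrow = length(dist_x), ncol = 1,
                       dimnames = list(NULL, "intercept")),
    distance = matrix(dist_x, ncol = 1, dimnames = list(NULL, "distance")),
    distance2 = matrix(dist_x^2, ncol = 1,
                       dimnames = list(NULL, "distance2")),
    diet = matrix(x$diet_pct, ncol = 1, dimnames = list(NULL, "diet")),
    bm = matrix(log10(x$body_mass_g), ncol = 1, dimnames = list(NULL, "bm")),
    habitat = matrix(as.numeric(x$habitat == "open"), ncol = 1,
                     dimnames = list(NULL, "habitat_open")),
    infratype = {
      lv <- infra_levels[-1]
      m <- sapply(lv, function(l) as.numeric(x$infra_type == l))
      m <- matrix(m, ncol = length(lv))
      colnames(m) <- paste0("infra_", lv)
      m
    },
    stop("unknown term: ", term)
  )
  base
}

#' Build a fixed-effects design matrix
#'
#' Expands a [moderator_spec()] into a numeric design matrix using
#' treatment contrasts (`habitat` reference `closed`, `infratype` reference
#' `non_traffic`; birds carry `power_line` as an extra level). Continuous
#' moderators are uncentered: distance as `log10` metres (clamped at 1 m),
#' body mass as `log10` grams, diet as raw percent in `[0, 100]`. Columns
#' follow the spec's term order.
#'
#' @param records data.frame with columns `distance_m`, `habitat`,
#'   `infra_type` and, as needed, `diet_pct`, `body_mass_g`.
#' @param spec a `moderator_spec`.
#' @param taxon_group taxon the model is for; determines the infrastructure
#'   levels and whether diet is permitted.
#' @return numeric matrix with labelled columns.
#' @export
build_design <- function(records, spec, taxon_group) {
  taxon_group <- match.arg(taxon_group, .taxon_groups)
  stopifnot(inherits(spec, "moderator_spec"))
  if (any(grepl("diet", spec$terms)) &&
      taxon_group %in% c("reptile", "amphibian"))
    stop("diet terms are not defined for reptiles or amphibians")
  if (any(grepl("diet", spec$terms)) && any(is.na(records$diet_pct)))
    stop("diet_pct missing for some records")
  dist_x <- transform_distance(records$distance_m)
  cols <- lapply(spec$terms, function(tm) {
    parts <- .main_of(tm)
    if (length(parts) == 1L) {
      .term_columns(tm, records, dist_x, taxon_group)
    } else {
      a <- .term_columns(parts[1], records, dist_x, taxon_group)
      b <- .term_columns(parts[2], records, dist_x, taxon_group)
      m <- a[, 1] * b
      m <- matrix(m, ncol = ncol(b))
      colnames(m) <- paste0(colnames(a)[1], ":", colnames(b))
      m
    }
  })
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  X
}

#' Enumerate candidate moderator specifications
#'
#' Generates every subset of a taxon's term menu that satisfies
#' marginality (always including the intercept-only model), for AICc-based
#' model selection. The default menus include distance (linear and
#' quadratic), habitat and infrastructure type for all taxa, and body mass
#' and diet (with distance interactions) where the trait is defined:
#' diet only for mammals and birds.
#'
#' @param taxon_group taxon name.
#' @param menu optional character vector of term names overriding the
#'   taxon's default menu.
#' @return list of `moderator_spec` objects, ordered by number of terms.
#' @export
enumerate_candidate_specs <- function(taxon_group = NULL, menu = NULL) {
  if (is.null(menu)) {
    taxon_group <- match.arg(taxon_group, .taxon_groups)
    menu <- switch(taxon_group,
      mammal = ,
      bird = setdiff(.term_order, "intercept"),
      reptile = ,
      amphibian = setdiff(.term_order,
                          c("intercept", "diet", "distance:diet",
                            "distance2:diet"))
    )
  }
  menu <- setdiff(menu, "intercept")
  n <- length(menu)
  specs <- list(moderator_spec())
  if (n == 0L) return(specs)
  for (mask in seq_len(2^n - 1L)) {
    terms <- menu[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    s <- tryCatch(moderator_spec(terms), error = function(e) NULL)
    if (!is.null(s)) specs[[length(specs) + 1L]] <- s
  }
  specs[order(vapply(specs, function(s) length(s$terms), numeric(1)))]
}

#' Random-effects grouping structure
#'
#' The five-component multilevel structure: observation-level residual
#' heterogeneity, clade (order for mammals and birds, family for reptiles
#' and amphibians), species nested in clade, data source, and study nested
#' in source.
#'
#' @param records data.frame with `comparison_id`, `clade`, `species_id`,
#'   `source_id`, `study_id`.
#' @return named list of factors (one per variance component), each with
#'   one entry per record: `observation`, `clade`, `species`, `source`,
#'   `study`.
#' @export
random_effects_groups <- function(records) {
  list(
    observation = factor(seq_len(nrow(records))),
    clade = factor(records$clade),
    species = factor(paste(records$clade, records$species_id, sep = "/")),
    source = factor(records$source_id),
    study = factor(paste(records$source_id, records$study_id, sep = "/"))
  )
}
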