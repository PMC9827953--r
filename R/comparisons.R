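# Fixed flat-CSV schema: one row per pairwise disturbed/control comparison.
.comparison_columns <- c(
  "comparison_id", "source_id", "study_id", "species_id", "taxon_group",
  "clade", "distance_m", "infra_type", "habitat", "mean_treat", "sd_treat",
  "n_treat", "mean_ctrl", "sd_ctrl", "n_ctrl", "scale_D", "body_mass_g",
  "diet_pct", "quality_a", "quality_b"
)

.taxon_groups <- c("mammal", "bird", "reptile", "amphibian")
.infra_types  <- c("non_traffic", "paved_road", "power_line", "unpaved_road")
.habitats     <- c("closed", "open")

.numeric_cols <- c(
  "distance_m", "mean_treat", "sd_treat", "n_treat", "mean_ctrl", "sd_ctrl",
  "n_ctrl", "scale_D", "body_mass_g", "diet_pct", "quality_a", "quality_b"
)

#' Validate pairwise abundance comparison records
#'
#' Checks every row of a comparison table against the structural invariants
#' of the data model: non-negative means and distances, sample sizes of at
#' least one per arm, positive reporting-scale constant and body mass,
#' closed vocabularies for taxon group, infrastructure type and habitat,
#' diet present exactly for mammals and birds, the bird-only power-line
#' level, and a consistent study-to-source mapping.
#'
#' @param x data.frame with the comparison schema (see
#'   [read_comparisons()]).
#' @return A list with components `valid` (the rows that pass), `rejected`
#'   (the rows that fail) and `diagnostics` (character vector, one message
#'   per rejected row naming the violated invariant).
#' @export
validate_comparisons <- function(x) {
  missing_cols <- setdiff(.comparison_columns, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(x)
  problems <- vector("list", n)
  add <- function(i, msg) problems[[i]] <<- c(problems[[i]], msg)

  for (i in seq_len(n)) {
    r <- x[i, ]
    if (is.na(r$taxon_group) || !(r$taxon_group %in% .taxon_groups))
      add(i, sprintf("taxon_group '%s' not in {%s}", r$taxon_group,
                     paste(.taxon_groups, collapse = ", ")))
    if (is.na(r$infra_type) || !(r$infra_type %in% .infra_types))
      add(i, sprintf("infra_type '%s' not recognised", r$infra_type))
    if (!is.na(r$infra_type) && identical(r$infra_type, "power_line") &&
        !is.na(r$taxon_group) && r$taxon_group != "bird")
      add(i, "power_line is a distinct level for birds only; map to non_traffic")
    if (is.na(r$habitat) || !(r$habitat %in% .habitats))
      add(i, sprintf("habitat '%s' not in {closed, open}", r$habitat))
    if (is.na(r$distance_m) || r$distance_m < 0)
      add(i, "distance_m must be >= 0")
    if (is.na(r$mean_treat) || r$mean_treat < 0)
      add(i, "mean_treat must be >= 0")
    if (is.na(r$mean_ctrl) || r$mean_ctrl < 0)
      add(i, "mean_ctrl must be >= 0")
    if (!is.na(r$sd_treat) && r$sd_treat < 0) add(i, "sd_treat must be >= 0")
    if (!is.na(r$sd_ctrl) && r$sd_ctrl < 0) add(i, "sd_ctrl must be >= 0")
    for (nm in c("n_treat", "n_ctrl")) {
      v <- r[[nm]]
      if (is.na(v) || v < 1 || v != round(v))
        add(i, sprintf("%s must be an integer >= 1", nm))
    }
    if (is.na(r$scale_D) || r$scale_D <= 0) add(i, "scale_D must be > 0")
    if (is.na(r$body_mass_g) || r$body_mass_g <= 0)
      add(i, "body_mass_g must be > 0")
    needs_diet <- !is.na(r$taxon_group) && r$taxon_group %in% c("mammal", "bird")
    if (needs_diet && is.na(r$diet_pct))
      add(i, "diet_pct required for mammals and birds")
    if (!is.na(r$diet_pct) && (r$diet_pct < 0 || r$diet_pct > 100))
      add(i, "diet_pct must lie in [0, 100]")
    for (nm in c("quality_a", "quality_b")) {
      v <- r[[nm]]
      if (!is.na(v) && !(v %in% c(0, 1)))
        add(i, sprintf("%s must be 0 or 1", nm))
    }
  }

  # every study belongs to exactly one source
  study_src <- unique(x[, c("study_id", "source_id")])
  dup <- study_src$study_id[duplicated(study_src$study_id)]
  if (length(dup) > 0L) {
    for (i in which(x$study_id %in% dup))
      add(i, sprintf("study_id '%s' maps to more than one source_id",
                     x$study_id[i]))
  }
  if (anyDuplicated(x$comparison_id)) {
    for (i in which(x$comparison_id %in%
                    x$comparison_id[duplicated(x$comparison_id)]))
      add(i, sprintf("duplicated comparison_id '%s'", x$comparison_id[i]))
  }

  bad <- which(!vapply(problems, is.null, logical(1)))
  diagnostics <- unlist(lapply(bad, function(i)
    sprintf("row %d (%s): %s", i, x$comparison_id[i],
            paste(problems[[i]], collapse = "; "))))
  list(
    valid = x[setdiff(seq_len(n), bad), , drop = FALSE],
    rejected = x[bad, , drop = FALSE],
    diagnostics = diagnostics %||% character(0)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read pairwise abundance comparisons from a flat CSV
#'
#' The expected file is one row per disturbed/control comparison with fixed
#' column names (`comparison_id, source_id, study_id, species_id,
#' taxon_group, clade, distance_m, infra_type, habitat, mean_treat,
#' sd_treat, n_treat, mean_ctrl, sd_ctrl, n_ctrl, scale_D, body_mass_g,
#' diet_pct, quality_a, quality_b`). Missing standard deviations are empty
#' cells and come back as `NA`, never 0; decimal separator is the point.
#'
#' @param path path to a CSV file.
#' @param reject_invalid drop rows that violate the record invariants
#'   (default `TRUE`); diagnostics are attached as the
#'   `"diagnostics"` attribute and emitted as a warning.
#' @return data.frame of validated comparison records.
#' @seealso [validate_comparisons()], [write_comparisons()]
#' @export
read_comparisons <- function(path, reject_invalid = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  missing_cols <- setdiff(.comparison_columns, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (nm in .numeric_cols) {
    if (!is.numeric(x[[nm]])) {
      coerced <- suppressWarnings(as.numeric(x[[nm]]))
      bad <- which(!is.na(x[[nm]]) & is.na(coerced))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric value in column '%s' at row(s) %s",
                     nm, paste(bad, collapse = ", ")))
      }
      x[[nm]] <- coerced
    }
  }
  x <- x[, .comparison_columns]
  if (!reject_invalid) return(x)
  v <- validate_comparisons(x)
  if (length(v$diagnostics) > 0L) {
    warning(sprintf("rejected %d row(s):\n%s", nrow(v$rejected),
                    paste(v$diagnostics, collapse = "\n")))
  }
  structure(v$valid, diagnostics = v$diagnostics)
}

#' Write comparison records to CSV
#'
#' Inverse of [read_comparisons()]: `read_comparisons(write_comparisons(x))`
#' returns the same record set. Missing values are written as empty cells.
#'
#' @param x data.frame of comparison records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_comparisons <- function(x, path) {
  utils::write.csv(x[, .comparison_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Default free-text label mappings for infrastructure and habitat
#'
#' The mapping encodes the classification used throughout: paved roads
#' (including highways), unpaved roads (dirt, gravel), power lines, and
#' non-traffic infrastructure (trails, seismic lines, pipelines); habitats
#' are open (grasslands, croplands, shrublands) or closed (forests).
#'
#' @return list with `infra` and `habitat` named character vectors mapping
#'   lower-case labels to canonical levels.
#' @export
default_label_mapping <- function() {
  infra <- c(
    "paved road" = "paved_road", "highway" = "paved_road",
    "motorway" = "paved_road", "secondary paved road" = "paved_road",
    "road" = "paved_road",
    "unpaved road" = "unpaved_road", "dirt road" = "unpaved_road",
    "gravel road" = "unpaved_road", "logging track" = "unpaved_road",
    "power line" = "power_line", "powerline" = "power_line",
    "transmission line" = "power_line",
    "trail" = "non_traffic", "seismic line" = "non_traffic",
    "pipeline" = "non_traffic", "non-traffic" = "non_traffic"
  )
  habitat <- c(
    "grassland" = "open", "cropland" = "open", "shrubland" = "open",
    "open" = "open",
    "forest" = "closed", "tropical forest" = "closed",
    "temperate forest" = "closed", "closed" = "closed"
  )
  list(infra = infra, habitat = habitat)
}

#' Classify free-text infrastructure and habitat labels
#'
#' Maps raw labels onto the closed vocabularies used by the models. Power
#' lines are a distinct infrastructure level for birds only; for mammals,
#' reptiles and amphibians they are combined with non-traffic
#' infrastructure.
#'
#' @param raw_infra free-text infrastructure label (e.g. "highway").
#' @param raw_habitat free-text habitat label (e.g. "tropical forest").
#' @param taxon_group one of `"mammal"`, `"bird"`, `"reptile"`,
#'   `"amphibian"`.
#' @param mapping label mapping table, see [default_label_mapping()].
#' @return list with elements `infra_type` and `habitat`.
#' @export
classify_levels <- function(raw_infra, raw_habitat, taxon_group,
                            mapping = default_label_mapping()) {
  taxon_group <- match.arg(taxon_group, .taxon_groups)
  ik <- tolower(trimws(raw_infra))
  hk <- tolower(trimws(raw_habitat))
  if (!(ik %in% names(mapping$infra)))
    stop("unmapped infrastructure label: '", raw_infra, "'")
  if (!(hk %in% names(mapping$habitat)))
    stop("unmapped habitat label: '", raw_habitat, "'")
  infra <- unname(mapping$infra[[ik]])
  if (infra == "power_line" && taxon_group != "bird") infra <- "non_traffic"
  list(infra_type = infra, habitat = unname(mapping$habitat[[hk]]))
}

#' Aggregate species traits to the genus level
#'
#' For genus-level abundance records, the trait value is the arithmetic
#' mean of body mass and diet across the member species.
#'
#' @param body_mass_g numeric vector of member body masses (g).
#' @param diet_pct numeric vector of member diet percentages, or `NULL`
#'   for taxa without a diet trait.
#' @return list with `body_mass_g` and `diet_pct` (NA when absent).
#' @export
aggregate_genus_traits <- function(body_mass_g, diet_pct = NULL) {
  if (length(body_mass_g) == 0L) stop("empty trait list")
  if (!is.null(diet_pct) && length(diet_pct) != length(body_mass_g))
    stop("trait vectors must have equal length")
  list(
    body_mass_g = mean(body_mass_g),
    diet_pct = if (is.null(diet_pct)) NA_real_ else mean(diet_pct)
  )
}

#' Subset records by data-quality criteria
#'
#' Two binary quality criteria accompany each record: `quality_a = 1` when
#' abundance is reported at the species (not genus-aggregate) level, and
#' `quality_b = 1` when the control site is explicitly undisturbed or
#' beyond the species' home range.
#'
#' @param records comparison data.frame.
#' @param drop_genus_aggregates drop records with `quality_a = 0`.
#' @param drop_unverified_controls drop records with `quality_b = 0`.
#' @return filtered data.frame.
#' @export
quality_subset <- function(records, drop_genus_aggregates = FALSE,
                           drop_unverified_controls = FALSE) {
  keep <- rep(TRUE, nrow(records))
  if (drop_genus_aggregates) keep <- keep & records$quality_a != 0
  if (drop_unverified_controls) keep <- keep & records$quality_b != 0
  records[keep, , drop = FALSE]
}
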