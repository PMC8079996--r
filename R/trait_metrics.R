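#' @useDynLib lifecube, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov coef optimize pnorm pt quantile rexp rnorm runif sd
#'   setNames var TukeyHSD lm optim
#' @importFrom utils read.csv write.csv
"_PACKAGE"

# Columns holding trait measurements (as opposed to identifiers).
.trait_fields <- c(
  "adult_body_mass", "litter_size", "litters_per_year",
  "mass_at_independence", "max_longevity", "female_maturity_age",
  "svl_min", "svl_max"
)

.clades <- c("Amphibia", "Reptilia", "Mammalia", "Aves")

#' Normalize species names for matching against tree tip labels
#'
#' Trims surrounding whitespace and replaces internal spaces with
#' underscores, the convention used by Newick tip labels.
#'
#' @param x character vector of binomial names.
#' @return character vector of normalized names.
#' @export
normalize_species_names <- function(x) {
  gsub(" +", "_", trimws(x))
}

.check_trait_table <- function(tab, name = "trait table") {
  if (!is.data.frame(tab)) stop(name, " must be a data.frame")
  if (!"species" %in% names(tab)) stop(name, " must have a 'species' column")
  dup <- unique(tab$species[duplicated(tab$species)])
  if (length(dup) > 0L) {
    stop("duplicate species in ", name, ": ", paste(dup, collapse = ", "))
  }
  for (f in intersect(.trait_fields, names(tab))) {
    bad <- which(!is.na(tab[[f]]) & tab[[f]] <= 0)
    if (length(bad) > 0L) {
      stop("non-positive values of '", f, "' in ", name, " (e.g. row ", bad[1L], ")")
    }
  }
  invisible(tab)
}

#' Read a delimited trait table
#'
#' Reads a CSV/TSV file with a header row and maps source-specific column
#' names onto the canonical trait schema (species, clade, adult_body_mass,
#' litter_size, litters_per_year, mass_at_independence, max_longevity,
#' female_maturity_age, svl_min, svl_max, and optionally order).
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical names to the
#'   column names used in the file; canonical names already present are kept.
#' @param sep field separator; guessed from the file extension by default.
#' @return a trait data.frame with normalized species names.
#' @export
read_trait_table <- function(path, column_map = NULL, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  }
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (src %in% names(tab) && !canon %in% names(tab)) {
        names(tab)[names(tab) == src] <- canon
      }
    }
  }
  tab$species <- normalize_species_names(tab$species)
  .check_trait_table(tab, basename(path))
  tab
}

#' Merge a primary and a supplementary trait table
#'
#' Species present in both tables keep every value of the primary table;
#' only fields missing (NA) in the primary are filled from the supplement.
#' Species present only in the supplement are appended whole. A
#' `<field>_source` column records per-field provenance (`"primary"`,
#' `"supplement"`, or NA when the value is absent everywhere).
#'
#' @param primary,supplement trait data.frames sharing a column schema and
#'   keyed by `species`.
#' @return merged trait data.frame with one row per species in the union.
#' @export
merge_trait_sources <- function(primary, supplement) {
  .check_trait_table(primary, "primary")
  .check_trait_table(supplement, "supplement")
  fields <- intersect(.trait_fields, union(names(primary), names(supplement)))
  miss_p <- setdiff(fields, names(primary))
  miss_s <- setdiff(fields, names(supplement))
  if (length(miss_p) > 0L || length(miss_s) > 0L) {
    stop("schema mismatch between primary and supplement: ",
         paste(unique(c(miss_p, miss_s)), collapse = ", "))
  }
  id_cols <- setdiff(names(primary), fields)

  out <- primary
  for (f in fields) {
    out[[paste0(f, "_source")]] <- ifelse(is.na(out[[f]]), NA_character_, "primary")
  }

  sup_idx <- match(out$species, supplement$species)
  for (f in fields) {
    fill <- is.na(out[[f]]) & !is.na(sup_idx) & !is.na(supplement[[f]][sup_idx])
    out[[f]][fill] <- supplement[[f]][sup_idx[fill]]
    out[[paste0(f, "_source")]][fill] <- "supplement"
  }

  new_sp <- setdiff(supplement$species, primary$species)
  if (length(new_sp) > 0L) {
    add <- supplement[match(new_sp, supplement$species), , drop = FALSE]
    for (col in setdiff(names(out), names(add))) add[[col]] <- NA
    for (f in fields) {
      add[[paste0(f, "_source")]] <- ifelse(is.na(add[[f]]), NA_character_, "supplement")
    }
    out <- rbind(out[names(out)], add[names(out)])
  }
  rownames(out) <- NULL
  out
}

#' Allometric parameters for snout-vent-length to body-mass conversion
#'
#' @param group taxonomic group the coefficients apply to ("Anura" or
#'   "Caudata").
#' @param a multiplicative coefficient (g per mm^b).
#' @param b allometric exponent (dimensionless).
#' @return an object of class `allometry_params`.
#' @export
allometry_params <- function(group = c("Anura", "Caudata"), a, b) {
  group <- match.arg(group)
  if (!is.numeric(a) || a <= 0) stop("allometric coefficient 'a' must be > 0")
  if (!is.numeric(b) || b <= 0) stop("allometric exponent 'b' must be > 0")
  structure(list(group = group, a = a, b = b), class = "allometry_params")
}

#' Convert snout-vent length to body mass by a power-law allometry
#'
#' @param svl snout-vent length in mm (vectorized).
#' @param params an [allometry_params()] object.
#' @return body mass in grams, `a * svl^b`.
#' @export
svl_to_mass <- function(svl, params) {
  stopifnot(inherits(params, "allometry_params"))
  if (any(!is.finite(svl)) || any(svl <= 0)) stop("svl must be positive")
  params$a * svl^params$b
}

#' Mean adult body mass from a snout-vent-length range
#'
#' Converts the minimum and maximum lengths to mass and averages the two,
#' giving an approximate mean adult mass for amphibians whose databases
#' report only a length range.
#'
#' @param svl_min,svl_max length range in mm, `0 < svl_min <= svl_max`.
#' @inheritParams svl_to_mass
#' @return mean of the two converted masses, grams.
#' @export
amphibian_mean_mass <- function(svl_min, svl_max, params) {
  if (any(svl_min > svl_max)) stop("svl_min must not exceed svl_max")
  (svl_to_mass(svl_min, params) + svl_to_mass(svl_max, params)) / 2
}

#' Adult lifespan from longevity and age at female maturity
#'
#' Adult lifespan is the time from reproductive maturity to death. With
#' maximum longevity as the endpoint it is `max_longevity -
#' female_maturity_age` (mode `"longevity_minus_maturity"`); mode
#' `"raw_longevity"` uses longevity unchanged for sensitivity runs.
#' Records with maturity >= longevity get NA and should be flagged upstream.
#'
#' @param record data.frame with `max_longevity` and `female_maturity_age`
#'   columns (years).
#' @param mode lifespan definition.
#' @return numeric vector of adult lifespans in years; NA where undefined.
#' @export
adult_lifespan <- function(record,
                           mode = c("longevity_minus_maturity", "raw_longevity")) {
  mode <- match.arg(mode)
  lon <- record$max_longevity
  mat <- record$female_maturity_age
  if (mode == "raw_longevity") return(lon)
  out <- lon - mat
  out[!is.na(out) & out <= 0] <- NA_real_
  out
}

#' Lifetime reproductive effort
#'
#' LRE = litter size x litters per year x mass at independence /
#' adult body mass x adult lifespan. Dimensionless: invariant to common
#' rescaling of the two masses and of the two times.
#'
#' @inheritParams adult_lifespan
#' @return numeric vector; NA where any component is missing.
#' @export
compute_lre <- function(record,
                        mode = c("longevity_minus_maturity", "raw_longevity")) {
  lifespan <- adult_lifespan(record, mode)
  record$litter_size * record$litters_per_year *
    record$mass_at_independence / record$adult_body_mass * lifespan
}

#' Relative reproductive lifespan
#'
#' RRL = adult lifespan / time to female maturity.
#'
#' @inheritParams adult_lifespan
#' @return numeric vector; NA where undefined.
#' @export
compute_rrl <- function(record,
                        mode = c("longevity_minus_maturity", "raw_longevity")) {
  adult_lifespan(record, mode) / record$female_maturity_age
}

#' Relative offspring size
#'
#' ROS = mass at independence / adult body mass.
#'
#' @inheritParams adult_lifespan
#' @return numeric vector; NA where a mass is missing.
#' @export
compute_ros <- function(record, mode = NULL) {
  record$mass_at_independence / record$adult_body_mass
}

#' Build the species-level table of dimensionless metrics
#'
#' Computes LRE, RRL and ROS for every species whose components are all
#' available, on natural and natural-log scale, and reports completeness:
#' how many species were retained and dropped per clade and which missing
#' field caused each drop. Species whose maturity age reaches or exceeds
#' their maximum longevity are excluded and flagged.
#'
#' @param records validated trait data.frame (see [merge_trait_sources()]).
#' @param adult_lifespan_mode passed to [adult_lifespan()].
#' @param amphibian_mass_mode `"max_mass"` uses `adult_body_mass` as given;
#'   `"mean_mass_from_svl"` replaces amphibian adult mass by
#'   [amphibian_mean_mass()] computed from `svl_min`/`svl_max` with
#'   group-specific allometries.
#' @param allometry named list of [allometry_params()] keyed by amphibian
#'   order (`Anura`, `Caudata`); required for `"mean_mass_from_svl"`.
#' @return list with `metrics` (data.frame: species, clade, mass_g, lre,
#'   rrl, ros, log_mass, log_lre, log_rrl, log_ros) and `report`
#'   (completeness summary).
#' @export
build_metric_table <- function(records,
                               adult_lifespan_mode = c("longevity_minus_maturity",
                                                       "raw_longevity"),
                               amphibian_mass_mode = c("max_mass",
                                                       "mean_mass_from_svl"),
                               allometry = NULL) {
  adult_lifespan_mode <- match.arg(adult_lifespan_mode)
  amphibian_mass_mode <- match.arg(amphibian_mass_mode)
  .check_trait_table(records)
  records$species <- normalize_species_names(records$species)

  if (amphibian_mass_mode == "mean_mass_from_svl") {
    if (is.null(allometry)) {
      stop("amphibian_mass_mode = 'mean_mass_from_svl' requires allometry params")
    }
    amph <- which(records$clade == "Amphibia" &
                    !is.na(records$svl_min) & !is.na(records$svl_max))
    for (i in amph) {
      grp <- if ("order" %in% names(records) && !is.na(records$order[i]) &&
                 records$order[i] %in% names(allometry)) records$order[i] else "Anura"
      records$adult_body_mass[i] <-
        amphibian_mean_mass(records$svl_min[i], records$svl_max[i], allometry[[grp]])
    }
  }

  flagged <- !is.na(records$max_longevity) & !is.na(records$female_maturity_age) &
    records$female_maturity_age >= records$max_longevity

  lre <- compute_lre(records, adult_lifespan_mode)
  rrl <- compute_rrl(records, adult_lifespan_mode)
  ros <- compute_ros(records)
  lre[flagged] <- NA_real_
  rrl[flagged] <- NA_real_

  keep <- !is.na(lre) & !is.na(rrl) & !is.na(ros)

  need <- list(
    lre = c("litter_size", "litters_per_year", "mass_at_independence",
            "adult_body_mass", "max_longevity", "female_maturity_age"),
    rrl = c("max_longevity", "female_maturity_age"),
    ros = c("mass_at_independence", "adult_body_mass")
  )
  missing_by_field <- list()
  for (f in unique(unlist(need))) {
    missing_by_field[[f]] <- sum(is.na(records[[f]]) & !keep)
  }

  clade_counts <- function(idx) {
    tab <- table(factor(records$clade[idx], levels = .clades))
    as.list(as.integer(tab)) |> setNames(.clades)
  }
  report <- list(
    n_input = nrow(records),
    n_retained = sum(keep),
    n_dropped = sum(!keep),
    retained_per_clade = clade_counts(keep),
    dropped_per_clade = clade_counts(!keep),
    dropped_missing_field = missing_by_field,
    flagged_maturity_ge_longevity = records$species[flagged],
    adult_lifespan_mode = adult_lifespan_mode,
    amphibian_mass_mode = amphibian_mass_mode
  )

  metrics <- data.frame(
    species = records$species[keep],
    clade = records$clade[keep],
    mass_g = records$adult_body_mass[keep],
    lre = lre[keep], rrl = rrl[keep], ros = ros[keep],
    stringsAsFactors = FALSE
  )
  metrics$log_mass <- log(metrics$mass_g)
  metrics$log_lre <- log(metrics$lre)
  metrics$log_rrl <- log(metrics$rrl)
  metrics$log_ros <- log(metrics$ros)
  metrics <- metrics[order(metrics$species), , drop = FALSE]
  rownames(metrics) <- NULL
  if (nrow(metrics) == 0L) warning("no species with all three metrics computable")
  list(metrics = metrics, report = report)
}

#' Write a metric table and its completeness report
#'
#' @param metric_table result of [build_metric_table()].
#' @param csv_path output CSV for the metric records.
#' @param report_path optional JSON path for the completeness report.
#' @return invisibly, the paths written.
#' @export
write_metric_table <- function(metric_table, csv_path, report_path = NULL) {
  write.csv(metric_table$metrics, csv_path, row.names = FALSE)
  if (!is.null(report_path)) {
    jsonlite::write_json(metric_table$report, report_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(csv_path, report_path))
}
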