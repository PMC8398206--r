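# Readers/writers for the tidy CSV/YAML/JSON schemas. CSV dialect: UTF-8,
# comma separator, "." decimal, mandatory header row. Method and basis
# names are normalized on read, so en-dash spellings from copy-pasted
# tables resolve against the catalog.

SPECIES_KINDS <- c("parent", "radical", "cation_radical", "anion_radical",
                   "anion", "h_atom")

#' Default reference-value table
#'
#' Reads the packaged reference config: one reference per scored property,
#' with units and provenance (`experimental` or `high_level_theory`).
#' Geometry references in the packaged file are synthetic stand-ins (see
#' the file's comments); energetic and Janak references follow the
#' published values.
#'
#' @param path optional path to a user YAML/JSON reference config.
#' @return data.frame `property`, `value`, `units`, `provenance`.
#' @export
default_references <- function(path = NULL) {
  if (is.null(path)) path <- catalog_path("references.yaml")
  read_references(path)
}

#' Read a reference config (YAML or JSON)
#'
#' @param path file path; format chosen by extension.
#' @return data.frame `property`, `value`, `units`, `provenance`.
#' @export
read_references <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- raw$references
  if (is.null(entries)) stop("reference config lacks a 'references' key", call. = FALSE)
  out <- do.call(rbind, lapply(entries, function(e) {
    stopifnot(!is.null(e$property), !is.null(e$value), !is.null(e$units))
    prov <- if (is.null(e$provenance)) "high_level_theory" else e$provenance
    if (!prov %in% c("experimental", "high_level_theory")) {
      stop("reference ", e$property, ": bad provenance '", prov, "'", call. = FALSE)
    }
    data.frame(property = e$property, value = as.numeric(e$value),
               units = e$units, provenance = prov)
  }))
  if (anyDuplicated(out$property)) {
    stop("duplicate reference entries: ",
         paste(out$property[duplicated(out$property)], collapse = ", "), call. = FALSE)
  }
  out
}

#' Write species-energetics records to the tidy CSV schema
#'
#' One row per (combination, species, site): columns `functional`,
#' `basis`, `species_kind`, `site` (empty where not applicable),
#' `enthalpy_hartree`, `eps_homo_hartree`, `eps_lumo_hartree` (orbital
#' energies on the parent row only).
#'
#' @param records list of [species_energetics()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_energetics <- function(records, path) {
  rows <- list()
  add <- function(f, b, kind, site, h, homo = NA_real_, lumo = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      functional = f, basis = b, species_kind = kind, site = site,
      enthalpy_hartree = h, eps_homo_hartree = homo, eps_lumo_hartree = lumo)
  }
  for (s in records) {
    stopifnot(inherits(s, "species_energetics"))
    if (!identical(s$units, "hartree")) {
      stop("write_energetics expects records in Hartree", call. = FALSE)
    }
    if (!is.null(s$h_parent)) {
      add(s$functional, s$basis, "parent", "", s$h_parent,
          if (is.null(s$eps_homo)) NA_real_ else s$eps_homo,
          if (is.null(s$eps_lumo)) NA_real_ else s$eps_lumo)
    }
    for (site in names(s$h_radical_by_site)) {
      add(s$functional, s$basis, "radical", site, s$h_radical_by_site[[site]])
    }
    if (!is.null(s$h_cation_radical)) add(s$functional, s$basis, "cation_radical", "", s$h_cation_radical)
    if (!is.null(s$h_anion_radical)) add(s$functional, s$basis, "anion_radical", "", s$h_anion_radical)
    for (site in names(s$h_anion_by_site)) {
      add(s$functional, s$basis, "anion", site, s$h_anion_by_site[[site]])
    }
    if (!is.null(s$h_h_atom)) add(s$functional, s$basis, "h_atom", "", s$h_h_atom)
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read species-energetics records from the tidy CSV schema
#'
#' Validates every row: known species kinds, no duplicate
#' (combination, species, site) cells, and — unless `allow_unknown` —
#' functional/basis names resolvable against the catalogs. Errors report
#' the offending row number.
#'
#' @param path CSV path (schema of [write_energetics()]).
#' @param allow_unknown accept names outside the packaged catalogs.
#' @return list of [species_energetics()].
#' @export
read_energetics <- function(path, allow_unknown = FALSE) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  needed <- c("functional", "basis", "species_kind", "site", "enthalpy_hartree")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("energetics file lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  df$site <- as.character(df$site)
  df$site[is.na(df$site)] <- ""
  bad <- which(!df$species_kind %in% SPECIES_KINDS)
  if (length(bad)) {
    stop("row ", bad[1] + 1L, ": unknown species_kind '", df$species_kind[bad[1]], "'",
         call. = FALSE)
  }
  keys <- paste(normalize_name(df$functional), normalize_name(df$basis),
                df$species_kind, df$site)
  if (anyDuplicated(keys)) {
    stop("row ", which(duplicated(keys))[1] + 1L,
         ": duplicate (combination, species, site) record", call. = FALSE)
  }
  if (!allow_unknown) {
    for (i in seq_len(nrow(df))) {
      tryCatch({
        lookup_functional(df$functional[i])
        lookup_basis(df$basis[i])
      }, error = function(e) {
        stop("row ", i + 1L, ": ", conditionMessage(e), call. = FALSE)
      })
    }
  }
  combos <- unique(df[, c("functional", "basis")])
  lapply(seq_len(nrow(combos)), function(i) {
    sub <- df[df$functional == combos$functional[i] & df$basis == combos$basis[i], ]
    pick <- function(kind) {
      r <- sub[sub$species_kind == kind, ]
      if (!nrow(r)) return(NULL)
      r$enthalpy_hartree[1]
    }
    pick_sites <- function(kind) {
      r <- sub[sub$species_kind == kind, ]
      if (!nrow(r)) return(NULL)
      stats::setNames(r$enthalpy_hartree, r$site)
    }
    parent <- sub[sub$species_kind == "parent", ]
    homo <- lumo <- NULL
    if (nrow(parent) && "eps_homo_hartree" %in% names(sub)) {
      if (is.finite(parent$eps_homo_hartree[1])) homo <- parent$eps_homo_hartree[1]
      if (is.finite(parent$eps_lumo_hartree[1])) lumo <- parent$eps_lumo_hartree[1]
    }
    species_energetics(
      functional = combos$functional[i], basis = combos$basis[i],
      h_parent = pick("parent"),
      h_radical_by_site = pick_sites("radical"),
      h_cation_radical = pick("cation_radical"),
      h_anion_radical = pick("anion_radical"),
      h_anion_by_site = pick_sites("anion"),
      h_h_atom = pick("h_atom"),
      eps_homo = homo, eps_lumo = lumo)
  })
}

#' Write a timing table to CSV
#'
#' @param timings data.frame with the [stage_summary()] input schema.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timings <- function(timings, path) {
  utils::write.csv(timings, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a timing table from CSV
#'
#' @param path CSV with columns `functional`, `basis`, `stage`,
#'   `total_cpu_time_s`, `n_instances`, `n_cores`.
#' @return data.frame.
#' @export
read_timings <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  needed <- c("functional", "basis", "stage", "total_cpu_time_s", "n_instances", "n_cores")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("timing file lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write an error table to CSV
#'
#' @param errors tidy error table (`functional`, `basis`, `property`,
#'   `epsilon`, optionally `units`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_errors <- function(errors, path) {
  check_error_table(errors)
  utils::write.csv(errors, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an error table from CSV
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_errors <- function(path) {
  check_error_table(utils::read.csv(path, fileEncoding = "UTF-8"))
}
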