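#' @title Functional and basis-set catalogs
#' @description The benchmark grid couples 11 density functionals with 14
#'   basis sets (154 combinations). Both catalogs ship as YAML under
#'   `inst/extdata/` so users can extend them with new methods; the loaders
#'   validate every record before use.
#' @name catalogs
NULL

.catalog_env <- new.env(parent = emptyenv())

#' Normalize a functional or basis-set name for lookup
#'
#' Strips hyphens, en-/em-dashes and whitespace, case-folds, and maps the
#' omega spellings ("wB97", "ωB97") onto one key, so that the spelling
#' variants that appear in the literature all resolve to the same catalog
#' entry.
#'
#' @param x character vector of names.
#' @return character vector of normalized keys.
#' @export
#' @examples
#' normalize_name(c("M06-2X", "m062x", "wB97X", "CAM–B3LYP"))
normalize_name <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("ω", "w", x)
  x <- gsub("[-‐‒–—− ]", "", x)
  x
}

catalog_path <- function(file) {
  path <- system.file("extdata", file, package = "dftbench")
  if (!nzchar(path)) stop("packaged catalog file not found: ", file, call. = FALSE)
  path
}

validate_functional <- function(f) {
  stopifnot(is.character(f$name), nzchar(f$name))
  if (!f$rung %in% c("GGA", "GH", "RSH")) {
    stop("functional ", f$name, ": rung must be GGA, GH or RSH", call. = FALSE)
  }
  pct <- c(f$hf_sr, f$hf_mr, f$hf_lr)
  if (any(!is.finite(pct)) || any(pct < 0) || any(pct > 100)) {
    stop("functional ", f$name, ": %HF fractions must lie in [0, 100]", call. = FALSE)
  }
  if (f$rung %in% c("GGA", "GH") && length(unique(pct)) != 1L) {
    stop("functional ", f$name, ": global hybrids (and GGAs) must carry one constant %HF across ranges",
         call. = FALSE)
  }
  f
}

validate_basis <- function(b) {
  stopifnot(is.character(b$name), nzchar(b$name))
  if (!b$family %in% c("Pople", "Dunning", "Ahlrich")) {
    stop("basis set ", b$name, ": unknown family ", b$family, call. = FALSE)
  }
  if (!is.numeric(b$nbf) || b$nbf <= 0 || b$nbf != round(b$nbf)) {
    stop("basis set ", b$name, ": nbf must be a positive integer", call. = FALSE)
  }
  if (!b$zeta %in% c("double", "triple")) {
    stop("basis set ", b$name, ": zeta must be 'double' or 'triple'", call. = FALSE)
  }
  stopifnot(is.logical(b$diffuse))
  b
}

load_catalog <- function(what = c("functionals", "basis_sets"), path = NULL) {
  what <- match.arg(what)
  if (is.null(path)) path <- catalog_path(paste0(what, ".yaml"))
  raw <- yaml::read_yaml(path)[[what]]
  if (is.null(raw)) stop("catalog file lacks a top-level '", what, "' key", call. = FALSE)
  validator <- if (what == "functionals") validate_functional else validate_basis
  entries <- lapply(raw, validator)
  names(entries) <- normalize_name(vapply(entries, `[[`, "", "name"))
  if (anyDuplicated(names(entries))) {
    stop("duplicate (after normalization) names in ", what, " catalog", call. = FALSE)
  }
  entries
}

get_catalog <- function(what) {
  key <- paste0("catalog_", what)
  if (is.null(.catalog_env[[key]])) {
    .catalog_env[[key]] <- load_catalog(what)
  }
  .catalog_env[[key]]
}

#' Functional catalog as a data frame
#'
#' @param path optional path to a user-supplied YAML catalog with the same
#'   schema as the packaged one; defaults to the packaged catalog of the 11
#'   benchmark functionals.
#' @return data.frame with columns `name`, `rung`, `meta`, `hf_sr`, `hf_mr`,
#'   `hf_lr` (percent exact exchange at short/middle/long range).
#' @export
#' @examples
#' functional_catalog()
functional_catalog <- function(path = NULL) {
  entries <- if (is.null(path)) get_catalog("functionals") else load_catalog("functionals", path)
  do.call(rbind, lapply(entries, function(f) {
    data.frame(name = f$name, rung = f$rung, meta = f$meta,
               hf_sr = f$hf_sr, hf_mr = f$hf_mr, hf_lr = f$hf_lr,
               row.names = NULL)
  }))
}

#' Basis-set catalog as a data frame
#'
#' @inheritParams functional_catalog
#' @return data.frame with columns `name`, `family`, `nbf` (number of basis
#'   functions assigned to the benchmark molecule), `zeta`
#'   (`"double"`/`"triple"`), `diffuse`.
#' @export
#' @examples
#' basis_catalog()
basis_catalog <- function(path = NULL) {
  entries <- if (is.null(path)) get_catalog("basis_sets") else load_catalog("basis_sets", path)
  do.call(rbind, lapply(entries, function(b) {
    data.frame(name = b$name, family = b$family, nbf = as.integer(b$nbf),
               zeta = b$zeta, diffuse = b$diffuse, row.names = NULL)
  }))
}

lookup_entry <- function(name, what, label) {
  entries <- get_catalog(what)
  key <- normalize_name(name)
  hit <- entries[[key]]
  if (is.null(hit)) {
    all_keys <- names(entries)
    d <- utils::adist(key, all_keys)[1, ]
    near <- vapply(entries[order(d)[seq_len(min(3L, length(d)))]], `[[`, "", "name")
    stop("unknown ", label, " '", name, "'; nearest catalog entries: ",
         paste(near, collapse = ", "), call. = FALSE)
  }
  hit
}

#' Look up a functional in the catalog
#'
#' Name matching is tolerant of hyphen/dash and omega-spelling variants
#' (see [normalize_name()]). Unknown names raise an error that reports the
#' nearest catalog entries.
#'
#' @param name functional name, e.g. `"M06-2X"` or `"wB97X"`.
#' @return list of class `functional_spec` with fields `name`, `rung`
#'   (`"GGA"`, `"GH"` or `"RSH"`), `meta`, and the exact-exchange
#'   percentages `hf_sr`, `hf_mr`, `hf_lr`.
#' @export
#' @examples
#' lookup_functional("M06-2X")$hf_sr # 54
lookup_functional <- function(name) {
  structure(lookup_entry(name, "functionals", "functional"),
            class = "functional_spec")
}

#' Look up a basis set in the catalog
#'
#' @param name basis-set name, e.g. `"6-311G(d,p)"` or `"aug-cc-pVTZ"`.
#' @return list of class `basis_spec` with fields `name`, `family`, `nbf`,
#'   `zeta`, `diffuse`.
#' @export
#' @examples
#' lookup_basis("aug-cc-pVTZ")$nbf # 782
lookup_basis <- function(name) {
  structure(lookup_entry(name, "basis_sets", "basis set"),
            class = "basis_spec")
}

#' Encode a functional/basis pair as the six regression features
#'
#' The feature vector couples the functional's exact-exchange percentages
#' with the basis-set descriptors: `SR`, `MR`, `LR` are %HF at short, middle
#' and long range on the raw 0-100 scale; `NBF` the basis-function count;
#' `zeta` is 1 for a double-zeta set (absence of double-zeta means
#' triple-zeta); `D` is 1 when diffuse functions are present, with single
#' and double diffusion collapsed into one indicator.
#'
#' @param functional a `functional_spec` or a functional name.
#' @param basis a `basis_spec` or a basis-set name.
#' @return named numeric vector `(SR, MR, LR, NBF, zeta, D)`.
#' @export
#' @examples
#' encode_features("M06-2X", "6-311G(d,p)") # 54, 54, 54, 282, 0, 0
encode_features <- function(functional, basis) {
  if (is.character(functional)) functional <- lookup_functional(functional)
  if (is.character(basis)) basis <- lookup_basis(basis)
  c(SR = as.numeric(functional$hf_sr),
    MR = as.numeric(functional$hf_mr),
    LR = as.numeric(functional$hf_lr),
    NBF = as.numeric(basis$nbf),
    zeta = as.numeric(basis$zeta == "double"),
    D = as.numeric(isTRUE(basis$diffuse)))
}

#' The full functional x basis-set combination grid
#'
#' Cross product of the two catalogs (11 x 14 = 154 combinations with the
#' packaged catalogs), with the encoded feature columns attached.
#'
#' @return data.frame with one row per combination: `functional`, `basis`,
#'   `SR`, `MR`, `LR`, `NBF`, `zeta`, `D`.
#' @export
#' @examples
#' nrow(combination_grid()) # 154
combination_grid <- function() {
  fc <- functional_catalog()
  bc <- basis_catalog()
  grid <- expand.grid(functional = fc$name, basis = bc$name,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  feats <- t(mapply(function(f, b) encode_features(f, b),
                    grid$functional, grid$basis))
  cbind(grid, as.data.frame(feats, row.names = NULL))
}

#' @export
print.functional_spec <- function(x, ...) {
  cat(sprintf("<functional> %s  rung=%s%s  %%HF(SR/MR/LR) = %g/%g/%g\n",
              x$name, x$rung, if (isTRUE(x$meta)) " (meta)" else "",
              x$hf_sr, x$hf_mr, x$hf_lr))
  invisible(x)
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("<basis set> %s  family=%s  NBF=%d  %s-zeta%s\n",
              x$name, x$family, as.integer(x$nbf), x$zeta,
              if (isTRUE(x$diffuse)) ", diffuse" else ""))
  invisible(x)
}
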