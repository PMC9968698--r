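# Putative metabolite annotation: molecular-formula masses, ESI adduct m/z,
# and ppm matching of observed features against a metabolite library.

# Monoisotopic masses of the most abundant isotope (Da), IUPAC/CODATA values
# to >= 9 significant figures. "D" is deuterium (2H). Electron mass included
# so that charged-species m/z can be computed exactly.
.atomic_masses <- c(
  H  = 1.00782503207,
  D  = 2.01410177785,
  C  = 12.0000000000,
  N  = 14.0030740048,
  O  = 15.9949146196,
  F  = 18.9984031627,
  Na = 22.9897692809,
  P  = 30.9737616320,
  S  = 31.9720710015,
  Cl = 34.9688527100,
  K  = 38.9637064864
)
.electron_mass <- 0.000548579909

#' Parse a Hill-notation molecular formula
#'
#' Converts a formula string such as `"C59H106O6"` into a named vector of
#' element counts. Deuterium is written `D`. Element symbols absent from the
#' package's monoisotopic mass table are rejected, as are malformed strings.
#'
#' @param text Formula string (Hill notation, no charges or isotope brackets).
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C10H12N2O3")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) return(integer(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    bad <- gsub("[A-Z][a-z]?[0-9]*", "", text)
    stop("malformed formula '", text, "': unparseable token '", bad, "'")
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                           sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(sym, names(.atomic_masses))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  counts <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Monoisotopic mass of a molecular formula
#'
#' @param counts Named element counts as returned by [parse_formula()], or a
#'   formula string, which is parsed first.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  if (!length(counts)) return(0)
  sum(.atomic_masses[names(counts)] * as.numeric(counts))
}

# Adduct table for singly charged ESI species. Each m/z shift is derived from
# the atomic and electron masses above, never stored as a literal: a cation
# loses one electron, an anion gains one. Hac is acetic acid (C2H4O2).
.adduct_table <- function() {
  am <- .atomic_masses
  e <- .electron_mass
  data.frame(
    adduct = c("[M+H]+", "[M+Na]+", "[M+NH4]+",
               "[M-H]-", "[M+Cl]-", "[M+Hac-H]-"),
    mode = rep(c("positive", "negative"), each = 3L),
    shift = c(
      am[["H"]] - e,
      am[["Na"]] - e,
      am[["N"]] + 4 * am[["H"]] - e,
      -(am[["H"]] - e),
      am[["Cl"]] + e,
      2 * am[["C"]] + 4 * am[["H"]] + 2 * am[["O"]] - am[["H"]] + e
    ),
    stringsAsFactors = FALSE
  )
}

#' List supported ESI adducts
#'
#' Three positive-mode adducts (\eqn{[M+H]^+}, \eqn{[M+Na]^+},
#' \eqn{[M+NH4]^+}) and three negative-mode adducts (\eqn{[M-H]^-},
#' \eqn{[M+Cl]^-}, \eqn{[M+Hac-H]^-}; Hac = acetic acid). All singly charged;
#' shifts account for the electron mass.
#'
#' @return Data frame with columns `adduct`, `mode`, `shift` (Da).
#' @export
adducts <- function() .adduct_table()

#' m/z of an adduct ion
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param adduct Adduct name, one of `adducts()$adduct`.
#' @return Ion m/z (Th).
#' @examples
#' adduct_mz(monoisotopic_mass("H2O"), "[M+H]+")
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  tab <- .adduct_table()
  i <- match(adduct, tab$adduct)
  if (anyNA(i)) stop("unknown adduct: ", paste(adduct[is.na(i)], collapse = ", "))
  neutral_mass + tab$shift[i]
}

#' Neutral mass recovered from an adduct ion m/z
#'
#' Exact inverse of [adduct_mz()].
#' @inheritParams adduct_mz
#' @param mz Observed or theoretical ion m/z (Th).
#' @export
neutral_mass_from_mz <- function(mz, adduct) {
  tab <- .adduct_table()
  i <- match(adduct, tab$adduct)
  if (anyNA(i)) stop("unknown adduct: ", paste(adduct[is.na(i)], collapse = ", "))
  mz - tab$shift[i]
}

#' Signed ppm mass error
#'
#' @param observed,theoretical m/z values (Th).
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}

#' Read a metabolite library from delimited text
#'
#' Expects at least columns `name` and `formula`; optional `mode`
#' (`positive`/`negative`/`both`, default `both`) and `id`. Extra columns are
#' ignored.
#'
#' @param path Path to a tab- or comma-delimited text file.
#' @return Data frame of library entries with a computed `neutral_mass` column.
#' @export
read_library <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lib <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("name", "formula")
  if (!all(req %in% names(lib)))
    stop("library must contain columns: ", paste(req, collapse = ", "))
  if (is.null(lib$mode)) lib$mode <- "both"
  if (is.null(lib$id)) lib$id <- NA_character_
  lib$neutral_mass <- vapply(lib$formula, monoisotopic_mass, numeric(1))
  if (any(lib$neutral_mass <= 0)) stop("library entry with non-positive mass")
  lib[c("name", "formula", "mode", "id", "neutral_mass")]
}

#' Match features against a metabolite library by adduct m/z
#'
#' Every (feature, library entry, adduct) combination whose theoretical ion
#' m/z lies within `tolerance_ppm` of the observed m/z is reported; the
#' boundary is inclusive. A feature may collect several annotations (isobaric
#' metabolites such as leucine/isoleucine are indistinguishable by m/z alone)
#' and all are kept.
#'
#' @param features Data frame with columns `feature_id` and `mz`.
#' @param library Data frame as returned by [read_library()].
#' @param tolerance_ppm Match tolerance in ppm (default 5).
#' @param mode `"positive"` or `"negative"`; selects the adduct set and the
#'   library entries whose ionisation mode is compatible.
#' @return Data frame of annotations sorted by absolute ppm error: feature id,
#'   observed m/z, library name/formula/id, adduct, theoretical m/z, signed
#'   ppm error.
#' @export
match_library <- function(features, library, tolerance_ppm = 5,
                          mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  empty <- data.frame(feature_id = character(0), mz = numeric(0),
                      name = character(0), formula = character(0),
                      id = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(library) || nrow(library) == 0L) {
    warning("empty metabolite library: no annotations possible")
    return(empty)
  }
  lib <- library[library$mode %in% c(mode, "both"), , drop = FALSE]
  ad <- .adduct_table()
  ad <- ad[ad$mode == mode, , drop = FALSE]
  if (nrow(lib) == 0L || nrow(features) == 0L) return(empty)
  out <- vector("list", nrow(ad))
  for (j in seq_len(nrow(ad))) {
    theo <- lib$neutral_mass + ad$shift[j]
    # all feature x entry pairs within tolerance for this adduct
    grid <- expand.grid(f = seq_len(nrow(features)), l = seq_len(nrow(lib)))
    ppm <- ppm_error(features$mz[grid$f], theo[grid$l])
    keep <- abs(ppm) <= tolerance_ppm
    if (!any(keep)) next
    g <- grid[keep, , drop = FALSE]
    out[[j]] <- data.frame(
      feature_id = as.character(features$feature_id[g$f]),
      mz = features$mz[g$f],
      name = lib$name[g$l], formula = lib$formula[g$l],
      id = as.character(lib$id[g$l]), adduct = ad$adduct[j],
      theoretical_mz = theo[g$l], ppm = ppm[keep],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty)
  res <- res[order(abs(res$ppm)), , drop = FALSE]
  rownames(res) <- NULL
  res
}
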