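#' Parse an empirical formula string
#'
#' Parses a Hill-style empirical formula such as `"C11H12N2O2"` into element
#' counts. Multi-letter element symbols (`Na`, `Cl`, ...) and multi-digit
#' counts are supported; an omitted count means 1.
#'
#' @param text Formula string, e.g. `"C6H12O6"`.
#' @return An object of class `empirical_formula`: a named integer vector of
#'   element counts.
#' @examples
#' parse_formula("C11H12N2O2")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  counts <- integer(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[2])) {
      stop(sprintf("malformed formula '%s' at position %d", text, pos),
           call. = FALSE)
    }
    sym <- m[2]
    if (!sym %in% names(.isotope_table)) {
      # retry with a one-letter symbol (e.g. "CO" is carbon + oxygen)
      sym1 <- substr(sym, 1, 1)
      if (nchar(sym) == 2L && sym1 %in% names(.isotope_table)) {
        sym <- sym1
        m[2] <- sym
        m[3] <- ""
        m[1] <- sym
      } else {
        stop(sprintf("unknown element '%s' in formula '%s' at position %d",
                     sym, text, pos), call. = FALSE)
      }
    }
    cnt <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + cnt
    pos <- pos + nchar(m[1])
  }
  if (sum(counts) < 1L) stop("formula contains no atoms", call. = FALSE)
  structure(counts, class = "empirical_formula")
}

#' Format an empirical formula in canonical Hill order
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically.
#'
#' @param formula An `empirical_formula`.
#' @return A single string.
#' @export
format_formula <- function(formula) {
  syms <- names(formula)
  hill <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  cnt <- unclass(formula)[hill]
  paste0(hill, ifelse(cnt == 1L, "", as.character(cnt)), collapse = "")
}

#' Monoisotopic mass of a neutral formula
#'
#' @param formula An `empirical_formula` (or formula string).
#' @return Mass in Da using the lightest isotope of each element.
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  sum(vapply(names(formula), function(sym) {
    formula[[sym]] * .isotope_table[[sym]]$mass[1]
  }, numeric(1)))
}

# Supported adduct kinds. Mass deltas are atom masses without an
# electron-mass term, matching the convention of the reference values this
# package reproduces (protonated C11H12N2O2 at m/z 205.0977 = M + m(H)).
# [M+] covers intrinsically charged species such as quaternary ammoniums.
.adduct_table <- list(
  "[M+H]"  = list(charge = 1L,  delta_atoms = c(H = 1L)),
  "[M+Na]" = list(charge = 1L,  delta_atoms = c(Na = 1L)),
  "[M-H]"  = list(charge = -1L, delta_atoms = c(H = -1L)),
  "[M+]"   = list(charge = 1L,  delta_atoms = integer(0))
)

#' Construct an adduct descriptor
#'
#' @param kind One of `"[M+H]"`, `"[M+Na]"`, `"[M-H]"`, `"[M+]"`. A Unicode
#'   minus in `[M-H]` is accepted.
#' @return Object of class `adduct` with fields `kind`, `charge`,
#'   `mass_delta_da`.
#' @export
adduct <- function(kind) {
  kind <- gsub("−", "-", kind)
  if (!kind %in% names(.adduct_table)) {
    stop(sprintf("unknown adduct kind '%s' (supported: %s)", kind,
                 paste(names(.adduct_table), collapse = ", ")), call. = FALSE)
  }
  spec <- .adduct_table[[kind]]
  delta <- 0
  for (sym in names(spec$delta_atoms)) {
    delta <- delta + spec$delta_atoms[[sym]] * .isotope_table[[sym]]$mass[1]
  }
  structure(list(kind = kind, charge = spec$charge, mass_delta_da = delta),
            class = "adduct")
}

#' Theoretical aggregated isotopic envelope
#'
#' Computes the unit-Da-binned isotopomer distribution of a neutral formula
#' by convolving per-element isotope patterns (each expressed over integer
#' neutron-number offsets), truncates it to `n_isotopomers` entries and
#' normalises so the most intense entry is 1.
#'
#' @param formula An `empirical_formula` or formula string.
#' @param n_isotopomers Number of aggregated isotopomer peaks to keep
#'   (default 5).
#' @return Object of class `isotopic_envelope` with fields `offsets_da`
#'   (approximate Da offsets from the monoisotopic peak, `k * 1.003355`) and
#'   `rel_intensities` (max-normalised).
#' @export
isotopic_envelope <- function(formula, n_isotopomers = 5L) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(n_isotopomers >= 1L)
  nmax <- as.integer(n_isotopomers)
  dist <- 1.0  # polynomial in the neutron-offset variable, constant term 1
  for (sym in names(formula)) {
    iso <- .isotope_table[[sym]]
    offs <- round(iso$mass - iso$mass[1])
    elem <- numeric(max(offs) + 1L)
    elem[offs + 1L] <- iso$abundance
    elem <- elem / sum(elem)
    dist <- .poly_mult(dist, .poly_pow(elem, formula[[sym]], nmax), nmax)
  }
  if (length(dist) < nmax) dist <- c(dist, numeric(nmax - length(dist)))
  dist <- dist[seq_len(nmax)]
  structure(list(
    offsets_da = (seq_len(nmax) - 1L) * .isotopomer_spacing_da,
    rel_intensities = dist / max(dist)
  ), class = "isotopic_envelope")
}

# truncated polynomial product (coefficient vectors, constant term first)
.poly_mult <- function(a, b, nmax) {
  la <- length(a); lb <- length(b)
  out <- numeric(min(la + lb - 1L, nmax))
  for (i in seq_len(la)) {
    jmax <- min(lb, nmax - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

# truncated polynomial power by squaring
.poly_pow <- function(p, k, nmax) {
  result <- 1.0
  base <- p
  while (k > 0L) {
    if (k %% 2L == 1L) result <- .poly_mult(result, base, nmax)
    base <- .poly_mult(base, base, nmax)
    k <- k %/% 2L
  }
  result
}

#' Build an analysis target from a formula and adduct
#'
#' The target m/z is `(monoisotopic neutral mass + adduct mass delta) /
#' |charge|`; the theoretical isotopic envelope is attached for scoring.
#'
#' @param formula `empirical_formula` or formula string.
#' @param adduct An `adduct` object or adduct kind string.
#' @param name Optional display name; defaults to the Hill formula.
#' @param n_isotopomers Envelope length passed to [isotopic_envelope()].
#' @return Object of class `ccs_target` with fields `name`, `formula`,
#'   `adduct`, `target_mz`, `envelope`.
#' @examples
#' tgt <- make_target("C11H12N2O2", "[M+H]")
#' tgt$target_mz  # 205.0977
#' @export
make_target <- function(formula, adduct, name = NULL, n_isotopomers = 5L) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (is.character(adduct)) adduct <- adduct(adduct)
  spec <- .adduct_table[[adduct$kind]]
  for (sym in names(spec$delta_atoms)) {
    have <- if (sym %in% names(formula)) formula[[sym]] else 0L
    if (have + spec$delta_atoms[[sym]] < 0L) {
      stop(sprintf("adduct %s removes %s from a formula without it",
                   adduct$kind, sym), call. = FALSE)
    }
  }
  mono <- monoisotopic_mass(formula)
  mz <- (mono + adduct$mass_delta_da) / abs(adduct$charge)
  if (mz <= 0) stop("non-positive target m/z", call. = FALSE)
  structure(list(
    name = if (is.null(name)) format_formula(formula) else name,
    formula = formula,
    adduct = adduct,
    target_mz = mz,
    envelope = isotopic_envelope(formula, n_isotopomers)
  ), class = "ccs_target")
}

#' Read a target list file
#'
#' CSV dialect: columns `name`, `formula`, `adducts` where `adducts` is a
#' semicolon-separated list of adduct kinds. A JSON array of objects with
#' the same fields (adducts as array or semicolon string) is also accepted.
#' Each (formula, adduct) pair becomes one target.
#'
#' @param path File path (`.csv` or `.json`).
#' @param n_isotopomers Envelope length per target.
#' @return List of `ccs_target` objects.
#' @export
read_target_list <- function(path, n_isotopomers = 5L) {
  if (!file.exists(path)) stop("target list file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    df <- as.data.frame(raw, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("name", "formula", "adducts")
  if (!all(need %in% names(df))) {
    stop("target list must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    kinds <- if (is.list(df$adducts)) unlist(df$adducts[i]) else
      strsplit(df$adducts[i], ";")[[1]]
    for (k in trimws(kinds)) {
      if (!nzchar(k)) next
      out[[length(out) + 1L]] <- make_target(df$formula[i], k,
                                             name = df$name[i],
                                             n_isotopomers = n_isotopomers)
    }
  }
  out
}
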