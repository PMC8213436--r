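# Monoisotopic element masses (IUPAC 2021, most abundant isotope), plus the
# proton and electron masses used to turn neutral masses into ion m/z.
# Kept in one place so every mass-dependent number in the package is auditable.
ELEMENT_MASSES <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.9637066420,
  Cl = 34.96885268
)

PROTON_MASS <- 1.007276466621
ELECTRON_MASS <- 0.000548579909

#' Monoisotopic masses of the supported elements
#'
#' Returns the bundled table of monoisotopic (most-abundant-isotope) atomic
#' masses used by every mass computation in the package.
#'
#' @return A tibble with columns `element` and `mass` (Da).
#' @export
#' @examples
#' element_masses()
element_masses <- function() {
  tibble::tibble(element = names(ELEMENT_MASSES), mass = unname(ELEMENT_MASSES))
}

#' Parse a molecular formula into element counts
#'
#' Accepts Hill-style concatenations of element symbols with optional integer
#' counts (e.g. `"C39H50O19"`, `"H2O"`). A missing count means 1; repeated
#' symbols are summed.
#'
#' @param formula A single formula string.
#' @return A named integer vector of element counts (only elements with
#'   count >= 1 are stored). The empty string parses to an empty vector.
#' @export
#' @examples
#' parse_formula("C39H50O19")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  counts <- integer(0)
  pos <- 1L
  n <- nchar(formula)
  while (pos <= n) {
    rest <- substr(formula, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || m[2] == "") {
      stop(sprintf("formula parse error in '%s' at position %d ('%s')",
                   formula, pos, substr(formula, pos, pos)), call. = FALSE)
    }
    sym <- m[2]
    # A two-letter match whose lowercase tail makes an unknown symbol may hide
    # a valid one-letter symbol; the mass table has no such pairs, so reject.
    if (!sym %in% names(ELEMENT_MASSES)) {
      stop(sprintf("unknown element symbol '%s' in '%s' at position %d",
                   sym, formula, pos), call. = FALSE)
    }
    cnt <- if (m[3] == "") 1L else suppressWarnings(as.integer(m[3]))
    if (is.na(cnt)) {
      stop(sprintf("invalid count in '%s' at position %d", formula, pos),
           call. = FALSE)
    }
    if (cnt > 0L) {
      counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + cnt
    }
    pos <- pos + nchar(m[1])
  }
  counts
}

#' Format element counts as a canonical Hill formula string
#'
#' Hill order: carbon first, then hydrogen, then all other elements
#' alphabetically; when no carbon is present, all elements alphabetically.
#'
#' @param counts Named integer vector as returned by [parse_formula()].
#' @return A single formula string (`""` for an empty vector).
#' @export
format_formula <- function(counts) {
  if (length(counts) == 0L) return("")
  stopifnot(!is.null(names(counts)), all(counts >= 1))
  syms <- names(counts)
  ord <- if ("C" %in% syms) {
    c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  } else {
    sort(syms)
  }
  paste0(ord, ifelse(counts[ord] == 1L, "", counts[ord]), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' @param x Either a formula string or a named count vector from
#'   [parse_formula()].
#' @return Mass in Da (sum of count times most-abundant-isotope mass).
#' @export
#' @examples
#' monoisotopic_mass("C39H50O19")
monoisotopic_mass <- function(x) {
  counts <- if (is.character(x)) parse_formula(x) else x
  if (length(counts) == 0L) return(0)
  unknown <- setdiff(names(counts), names(ELEMENT_MASSES))
  if (length(unknown) > 0L) {
    stop("no monoisotopic mass for element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(ELEMENT_MASSES[names(counts)] * as.numeric(counts))
}

# All ions in scope are singly charged; an adduct is m/z = multiplicity * M +
# delta, with delta assembled from proton/atom/electron masses below so that
# electron bookkeeping is explicit.
.adduct_registry <- function() {
  na_d <- unname(ELEMENT_MASSES["Na"]) - ELECTRON_MASS
  k_d <- unname(ELEMENT_MASSES["K"]) - ELECTRON_MASS
  formate <- monoisotopic_mass(c(C = 1L, H = 1L, O = 2L)) + ELECTRON_MASS
  tibble::tibble(
    label = c("[M+H]+", "[M+K]+", "[M+Na]+", "[2M+H]+", "[M-e]+",
              "[M+COOH]-", "[M-H]-", "[2M-H]-"),
    polarity = c(rep("+", 5L), rep("-", 3L)),
    multiplicity = c(1L, 1L, 1L, 2L, 1L, 1L, 1L, 2L),
    delta = c(PROTON_MASS, k_d, na_d, PROTON_MASS, -ELECTRON_MASS,
              formate, -PROTON_MASS, -PROTON_MASS)
  )
}

#' Registered electrospray adduct rules
#'
#' The positive-mode set ([M+H]+, [M+K]+, [M+Na]+, [2M+H]+, [M-e]+) and
#' negative-mode set ([M+COOH]-, [M-H]-, [2M-H]-) used for library matching.
#' [M-e]+ is the radical cation (M minus one electron); [M+COOH]- is the
#' formate adduct (M plus the CHO2 anion).
#'
#' @param polarity Optional `"+"` or `"-"` to restrict the table.
#' @return A tibble with columns `label`, `polarity`, `multiplicity`, `delta`
#'   where m/z = `multiplicity * M + delta` for a neutral monoisotopic mass M.
#' @export
#' @examples
#' adduct_rules("+")
adduct_rules <- function(polarity = NULL) {
  rules <- .adduct_registry()
  if (!is.null(polarity)) {
    stopifnot(polarity %in% c("+", "-"))
    rules <- rules[rules$polarity == polarity, ]
  }
  rules
}

# Tolerate the typographic minus often pasted from reports.
.normalize_adduct_label <- function(label) {
  gsub("−", "-", label)
}

#' Theoretical m/z of an adduct ion
#'
#' @param M Neutral monoisotopic mass in Da (vectorized, all > 0).
#' @param rule Adduct label (e.g. `"[M+H]+"`) or a one-row slice of
#'   [adduct_rules()].
#' @return Theoretical m/z, `multiplicity * M + delta`.
#' @export
#' @examples
#' adduct_mz(monoisotopic_mass("C39H50O19"), "[M+H]+")
adduct_mz <- function(M, rule) {
  stopifnot(is.numeric(M), all(M > 0))
  if (is.character(rule)) {
    lab <- .normalize_adduct_label(rule)
    rules <- .adduct_registry()
    hit <- rules[rules$label == lab, ]
    if (nrow(hit) != 1L) {
      stop("unregistered adduct label: ", rule, call. = FALSE)
    }
    rule <- hit
  }
  rule$multiplicity * M + rule$delta
}

#' Bundled neutral-loss table for fragment assignment
#'
#' Common neutral losses of glycosylated natural products: rhamnose residue
#' (rha, C6H10O4), glucose residue (Glc, C6H10O5), water, carbon dioxide, and
#' the small aglycone losses C4H7, C4H8O4 and C3H6O3.
#'
#' @return A tibble with columns `label`, `formula`, `mass` (Da); `mass` is
#'   always `monoisotopic_mass(formula)`.
#' @export
neutral_losses <- function() {
  tbl <- tibble::tibble(
    label = c("rha", "Glc", "H2O", "CO2", "C4H7", "C4H8O4", "C3H6O3"),
    formula = c("C6H10O4", "C6H10O5", "H2O", "CO2", "C4H7", "C4H8O4", "C3H6O3")
  )
  tbl$mass <- vapply(tbl$formula, monoisotopic_mass, numeric(1),
                     USE.NAMES = FALSE)
  tbl
}
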