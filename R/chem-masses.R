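# Monoisotopic atomic masses (IUPAC/CODATA), the proton mass used for
# charged-species m/z, and the C13-C12 spacing used for isotope envelopes.

#' @keywords internal
ATOMIC_MASS <- c(
  H = 1.007825032, C = 12.000000000, N = 14.003074005, O = 15.994914620,
  S = 31.972071174, P = 30.973761998, Se = 79.916521800,
  Na = 22.989769282, K = 38.963706487, Ca = 39.962590866,
  Fe = 55.934936330, Zn = 63.929142010
)

#' @keywords internal
PROTON_MASS <- 1.00727646

#' @keywords internal
ISOTOPE_SPACING <- 1.0033548

#' @keywords internal
WATER_MASS <- 2 * 1.007825032 + 15.994914620

# Monoisotopic residue masses for the 20 canonical amino acids
# (peptide-bond residues, i.e. amino acid minus water).
#' @keywords internal
RESIDUE_MASS <- c(
  G =  57.02146372, A =  71.03711379, S =  87.03202841, P =  97.05276385,
  V =  99.06841392, T = 101.04767847, C = 103.00918496, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841392, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

#' Parse a molecular formula into element counts
#'
#' Accepts compact Hill-style formulas such as `"C4H7NO"` or `"C5H5NO2"`.
#' Element symbols are one capital letter optionally followed by a lower-case
#' letter; a missing count means 1.
#'
#' @param formula Character scalar, e.g. `"C4H7NO"`.
#' @return A named integer vector of element counts.
#' @examples
#' parse_formula("C4H7NO")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (formula == "") {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("malformed formula: ", formula, call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- as.integer(sub("^[A-Za-z]+", "", tokens))
  cnt[is.na(cnt)] <- 1L
  counts <- tapply(cnt, sym, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Monoisotopic mass of an element composition
#'
#' @param composition Either a formula string (see [parse_formula()]) or a
#'   named integer vector of element counts.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C4H7NO")   # Bu, the DSBU signature fragment
#' monoisotopic_mass("C5H5NO2")  # BuUr
#' @export
monoisotopic_mass <- function(composition) {
  if (is.character(composition)) composition <- parse_formula(composition)
  if (length(composition) == 0L) return(0)
  if (any(composition < 0)) stop("negative element count", call. = FALSE)
  unknown <- setdiff(names(composition), names(ATOMIC_MASS))
  if (length(unknown) > 0L) {
    stop("unknown element symbol: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(ATOMIC_MASS[names(composition)] * as.numeric(composition))
}

#' Construct a peptide
#'
#' A peptide is a sequence over the 20 canonical amino-acid letters plus
#' optional fixed modifications (applied to every matching residue) and
#' variable modifications (applied at explicit 1-based positions).
#'
#' @param sequence Character scalar of amino-acid letters.
#' @param fixed_mods Named numeric vector: residue letter -> mass delta (Da).
#'   Default is carbamidomethylation of cysteine (+57.02146 Da, iodoacetamide).
#' @param variable_mods Numeric vector named by 1-based position -> mass delta
#'   (Da), e.g. `c("3" = 15.99491)` for oxidised Met at position 3.
#' @return An object of class `xl_peptide`.
#' @examples
#' peptide("KFWGK")
#' peptide("ACDMK", variable_mods = c("4" = 15.99491))
#' @export
peptide <- function(sequence, fixed_mods = c(C = 57.02146), variable_mods = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  residues <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(residues, names(RESIDUE_MASS))
  if (length(unknown) > 0L) {
    stop("unknown residue letter: ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(variable_mods) && length(variable_mods) > 0L) {
    pos <- as.integer(names(variable_mods))
    if (anyNA(pos) || any(pos < 1L) || any(pos > length(residues))) {
      stop("variable modification position outside peptide", call. = FALSE)
    }
  }
  structure(
    list(sequence = sequence,
         fixed_mods = fixed_mods %||% stats::setNames(numeric(0), character(0)),
         variable_mods = variable_mods %||% stats::setNames(numeric(0), character(0))),
    class = "xl_peptide"
  )
}

#' @export
print.xl_peptide <- function(x, ...) {
  cat("<peptide> ", x$sequence, "  mass ",
      format(peptide_mass(x), nsmall = 5), " Da\n", sep = "")
  invisible(x)
}

# Per-residue mass vector including fixed and variable mods; used by both
# peptide_mass() and the fragment enumerator so the two can never disagree.
residue_masses_of <- function(p) {
  residues <- strsplit(p$sequence, "")[[1]]
  m <- RESIDUE_MASS[residues]
  for (letter in names(p$fixed_mods)) {
    m[residues == letter] <- m[residues == letter] + p$fixed_mods[[letter]]
  }
  if (length(p$variable_mods) > 0L) {
    pos <- as.integer(names(p$variable_mods))
    m[pos] <- m[pos] + as.numeric(p$variable_mods)
  }
  unname(m)
}

#' Neutral monoisotopic mass of a peptide
#'
#' Sum of (modified) residue masses plus one water.
#'
#' @param p An [peptide()] object or a plain sequence string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("KFWGK")
#' @export
peptide_mass <- function(p) {
  if (is.character(p)) p <- peptide(p, fixed_mods = c(C = 57.02146))
  stopifnot(inherits(p, "xl_peptide"))
  sum(residue_masses_of(p)) + WATER_MASS
}

#' Cross-linker specification
#'
#' Describes an MS-cleavable cross-linker by its intact mass (added to the sum
#' of the two peptide masses), its two gas-phase cleavage fragments, and the
#' residues it reacts with. The default is DSBU (disuccinimidyl dibutyric
#' urea), whose urea bond cleaves into the complementary Bu (C4H7NO) and BuUr
#' (C5H5NO2) modifications - the diagnostic doublet used to recognise
#' cross-linked spectra.
#'
#' @param name Linker name.
#' @param fragment_a,fragment_b Name and formula of the two cleavage products.
#' @param intact_mass Intact linker mass in Da; defaults to the sum of the two
#'   fragment masses (mass conservation across the cleavable bond).
#' @param reactive_residues Residue letters the linker attacks.
#' @param n_term Logical; can the linker react with a protein/peptide N-terminus?
#' @return An object of class `xl_linker`.
#' @examples
#' dsbu_linker()
#' @export
linker_spec <- function(name = "DSBU",
                        fragment_a = c(Bu = "C4H7NO"),
                        fragment_b = c(BuUr = "C5H5NO2"),
                        intact_mass = NULL,
                        reactive_residues = c("K", "S", "T", "Y"),
                        n_term = TRUE) {
  fa <- monoisotopic_mass(unname(fragment_a))
  fb <- monoisotopic_mass(unname(fragment_b))
  if (is.null(intact_mass)) intact_mass <- fa + fb
  if (abs(fa + fb - intact_mass) > 1e-4) {
    stop("cleavable-linker mass conservation violated: ",
         "fragment masses sum to ", format(fa + fb),
         " but intact mass is ", format(intact_mass), call. = FALSE)
  }
  structure(
    list(name = name,
         fragment_a_name = names(fragment_a) %||% "A",
         fragment_a_mass = fa,
         fragment_b_name = names(fragment_b) %||% "B",
         fragment_b_mass = fb,
         intact_mass = intact_mass,
         reactive_residues = reactive_residues,
         n_term = n_term),
    class = "xl_linker"
  )
}

#' @rdname linker_spec
#' @export
dsbu_linker <- function() linker_spec()

#' @export
print.xl_linker <- function(x, ...) {
  cat("<linker> ", x$name, "  intact ", format(x$intact_mass, nsmall = 5),
      " Da  (", x$fragment_a_name, " + ", x$fragment_b_name, ")\n",
      "  reactive: ", paste(x$reactive_residues, collapse = ""),
      if (x$n_term) " + N-terminus", "\n", sep = "")
  invisible(x)
}

# Is position `pos` of peptide `p` linkable under `linker`?
is_reactive_site <- function(p, pos, linker) {
  residues <- strsplit(p$sequence, "")[[1]]
  if (pos < 1L || pos > length(residues)) return(FALSE)
  residues[pos] %in% linker$reactive_residues || (pos == 1L && linker$n_term)
}

#' Construct a cross-link between two peptides
#'
#' The alpha/beta labelling is conventional only: masses and fragment sets are
#' invariant under swapping the two peptides.
#'
#' @param alpha,beta [peptide()] objects or sequence strings.
#' @param pos_alpha,pos_beta 1-based link positions within each peptide; must
#'   be a reactive residue of the linker, or position 1 (N-terminal linkage).
#' @param linker An [linker_spec()] object; default DSBU.
#' @return An object of class `xl_crosslink`.
#' @examples
#' crosslink("KQTALVELLK", "KFWGK", 1, 1)
#' @export
crosslink <- function(alpha, beta, pos_alpha, pos_beta, linker = dsbu_linker()) {
  if (is.character(alpha)) alpha <- peptide(alpha)
  if (is.character(beta)) beta <- peptide(beta)
  stopifnot(inherits(alpha, "xl_peptide"), inherits(beta, "xl_peptide"),
            inherits(linker, "xl_linker"))
  if (!is_reactive_site(alpha, pos_alpha, linker)) {
    stop("link position ", pos_alpha, " of ", alpha$sequence,
         " is not a reactive site for ", linker$name, call. = FALSE)
  }
  if (!is_reactive_site(beta, pos_beta, linker)) {
    stop("link position ", pos_beta, " of ", beta$sequence,
         " is not a reactive site for ", linker$name, call. = FALSE)
  }
  structure(
    list(alpha = alpha, beta = beta,
         pos_alpha = as.integer(pos_alpha), pos_beta = as.integer(pos_beta),
         linker = linker),
    class = "xl_crosslink"
  )
}

#' @export
print.xl_crosslink <- function(x, ...) {
  cat("<crosslink> ", x$alpha$sequence, "-", x$beta$sequence,
      "-(", x$linker$name, "@", x$pos_alpha, ",", x$pos_beta, ")  mass ",
      format(crosslink_mass(x), nsmall = 5), " Da\n", sep = "")
  invisible(x)
}

#' Neutral mass of a cross-linked peptide pair
#'
#' `mass(alpha) + mass(beta) + intact linker mass`.
#'
#' @param xl An [crosslink()] object.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' crosslink_mass(crosslink("KQTALVELLK", "KFWGK", 1, 1))
#' @export
crosslink_mass <- function(xl) {
  stopifnot(inherits(xl, "xl_crosslink"))
  peptide_mass(xl$alpha) + peptide_mass(xl$beta) + xl$linker$intact_mass
}

#' m/z of a protonated species
#'
#' @param neutral_mass Neutral mass in Da.
#' @param z Positive integer charge.
#' @return `(neutral_mass + z * 1.00727646) / z` in Th.
#' @examples
#' precursor_mz(2002.16153, 3)
#' @export
precursor_mz <- function(neutral_mass, z) {
  if (any(z < 1) || any(z != round(z))) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  (neutral_mass + z * PROTON_MASS) / z
}

#' m/z of the k-th isotope peak
#'
#' Uses the averagine C13-C12 spacing convention (1.0033548 Da / z per
#' isotope); fine-structure envelopes are not modelled.
#'
#' @param mono_mz Monoisotopic m/z in Th.
#' @param z Positive integer charge.
#' @param k Isotope index; 0 is the monoisotopic peak.
#' @return m/z in Th.
#' @examples
#' isotope_mz(668.39445, 3, 0:2)
#' @export
isotope_mz <- function(mono_mz, z, k) {
  if (any(z < 1)) stop("charge must be >= 1", call. = FALSE)
  if (any(k < 0)) stop("isotope index must be >= 0", call. = FALSE)
  mono_mz + k * ISOTOPE_SPACING / z
}

#' Enumerate fragment ions of a cross-linked peptide pair
#'
#' For each of the two peptides every a-, b- and y-ion ordinal 1..len-1 is
#' produced. Fragments that do not span the link position carry no linker mass
#' (`linker_state = "none"`). Fragments spanning the link are emitted in three
#' variants: `"intact"` (full linker plus the complete partner peptide),
#' and the cleavable doublet `"retains_Bu"` / `"retains_BuUr"` (the fragment
#' keeps one cleavage product of the urea bond). All charges 1..`max_charge`
#' are emitted.
#'
#' @param xl An [crosslink()] object.
#' @param max_charge Maximum fragment charge state.
#' @param series Ion series to enumerate, subset of `c("a", "b", "y")`.
#' @return A tibble with columns `source_peptide` (`"alpha"`/`"beta"`),
#'   `series`, `ordinal`, `linker_state`, `charge`, `neutral_mass`, `mz`,
#'   ordered by (peptide, series, ordinal, state, charge).
#' @examples
#' fragment_ions(crosslink("KQTALVELLK", "KFWGK", 1, 1), max_charge = 2)
#' @export
fragment_ions <- function(xl, max_charge = 2L, series = c("a", "b", "y")) {
  stopifnot(inherits(xl, "xl_crosslink"), max_charge >= 1L)
  series <- match.arg(series, c("a", "b", "y"), several.ok = TRUE)
  # CO mass: a-ion = b-ion - CO
  co <- ATOMIC_MASS[["C"]] + ATOMIC_MASS[["O"]]
  one_peptide <- function(which) {
    p <- if (which == "alpha") xl$alpha else xl$beta
    partner <- if (which == "alpha") xl$beta else xl$alpha
    link_pos <- if (which == "alpha") xl$pos_alpha else xl$pos_beta
    rm <- residue_masses_of(p)
    n <- length(rm)
    prefix <- cumsum(rm)
    rows <- list()
    for (s in series) {
      for (ord in seq_len(n - 1L)) {
        # residues covered by this fragment
        if (s %in% c("a", "b")) {
          base <- prefix[ord]                   # b ion: sum of first ord residues
          if (s == "a") base <- base - co
          spans <- link_pos <= ord
        } else {
          base <- prefix[n] - prefix[n - ord] + WATER_MASS  # y ion
          spans <- link_pos > n - ord
        }
        if (!spans) {
          states <- "none"
          masses <- base
        } else {
          states <- c("intact", "retains_Bu", "retains_BuUr")
          masses <- c(
            base + xl$linker$intact_mass + peptide_mass(partner),
            base + xl$linker$fragment_a_mass,
            base + xl$linker$fragment_b_mass
          )
        }
        for (i in seq_along(states)) {
          rows[[length(rows) + 1L]] <- list(
            source_peptide = which, series = s, ordinal = ord,
            linker_state = states[i], neutral_mass = masses[i]
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  }
  frags <- dplyr::bind_rows(one_peptide("alpha"), one_peptide("beta"))
  frags <- tidyr::expand_grid(frags, charge = seq_len(max_charge))
  frags$mz <- precursor_mz(frags$neutral_mass, frags$charge)
  state_order <- c("none", "intact", "retains_Bu", "retains_BuUr")
  dplyr::arrange(
    tibble::as_tibble(frags),
    .data$source_peptide,
    factor(.data$series, levels = c("a", "b", "y")),
    .data$ordinal,
    factor(.data$linker_state, levels = state_order),
    .data$charge
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
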