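FORMATIONS <- c("autopolyploid", "allopolyploid", "autopolyploid_extant")
INHERITANCES <- c("tetrasomic", "disomic", "heterosomic")
MIGRATIONS <- c("none", "unidirectional_dip_to_AB", "bidirectional_AB",
                "unidirectional_dip_to_A", "unidirectional_dip_to_B")

#' Define a polyploid speciation scenario
#'
#' A scenario is the qualitative part of a model: how the tetraploid formed
#' (whole-genome duplication of an extinct sister lineage, duplication of the
#' extant diploid itself, or hybrid formation between the diploid and the
#' extinct lineage), how its four chromosome copies segregate (tetrasomic,
#' disomic, or a per-locus heterosomic mixture), and which interploid
#' migration routes are open between the present and the duplication event.
#'
#' @param formation One of `"autopolyploid"`, `"allopolyploid"`,
#'   `"autopolyploid_extant"`.
#' @param inheritance One of `"tetrasomic"`, `"disomic"`, `"heterosomic"`.
#' @param migration One of `"none"`, `"unidirectional_dip_to_AB"`,
#'   `"bidirectional_AB"`, `"unidirectional_dip_to_A"`,
#'   `"unidirectional_dip_to_B"`.
#' @return An object of class `polyploid_scenario`.
#' @export
polyploid_scenario <- function(formation = "autopolyploid",
                               inheritance = "tetrasomic",
                               migration = "none") {
  formation <- match.arg(formation, FORMATIONS)
  inheritance <- match.arg(inheritance, INHERITANCES)
  migration <- match.arg(migration, MIGRATIONS)
  structure(list(formation = formation, inheritance = inheritance,
                 migration = migration),
            class = "polyploid_scenario")
}

#' @export
print.polyploid_scenario <- function(x, ...) {
  cat("<polyploid_scenario>", scenario_key(x), "\n")
  invisible(x)
}

#' Compact scenario key
#' @param scenario A `polyploid_scenario`.
#' @return A string `formation.inheritance.migration`.
#' @export
scenario_key <- function(scenario) {
  paste(scenario$formation, scenario$inheritance, scenario$migration,
        sep = ".")
}

#' The default six-model comparison set
#'
#' Auto- and allopolyploid formation crossed with no migration, unidirectional
#' diploid-to-both-subgenomes migration, and asymmetric bidirectional
#' migration, all with tetrasomic inheritance.
#'
#' @return A named list of six `polyploid_scenario` objects.
#' @export
default_model_set <- function() {
  out <- list()
  for (f in c("autopolyploid", "allopolyploid"))
    for (m in c("none", "unidirectional_dip_to_AB", "bidirectional_AB")) {
      sc <- polyploid_scenario(f, "tetrasomic", m)
      out[[scenario_key(sc)]] <- sc
    }
  out
}

#' Numeric parameters of a polyploid speciation model
#'
#' Sizes are effective gene-copy counts per deme; times are in years before
#' present with `T_WGD <= T_split`; migration parameters are per-generation
#' migrant fractions active only between the present and the duplication
#' event. `generation_time` converts years to coalescent generations (the
#' source system's generation time is not published; 2 years is the package
#' default for a temperate treefrog).
#'
#' @param N_dip,N_ext,N_tet,N_anc Deme sizes in gene copies (> 0).
#' @param T_split Years since the progenitor lineage split from the extant
#'   diploid.
#' @param T_WGD Years since whole-genome duplication (`0 < T_WGD <= T_split`).
#' @param m_dip_to_A,m_dip_to_B Forward migrant fraction from the diploid
#'   into tetraploid subgenome A / B, per generation, in \[0, 0.5).
#' @param m_A_to_dip,m_B_to_dip Forward migrant fraction from subgenome A / B
#'   into the diploid, per generation.
#' @param n_disomic_loci Number of disomically inherited loci in a
#'   heterosomic dataset (0 unless inheritance is heterosomic).
#' @param generation_time Years per generation.
#' @return An object of class `scenario_parameters` (a named list).
#' @export
scenario_parameters <- function(N_dip = 2e5, N_ext = 1e5, N_tet = 1e5,
                                N_anc = 2e5, T_split = 2.88e5, T_WGD = 1e5,
                                m_dip_to_A = 0, m_dip_to_B = 0,
                                m_A_to_dip = 0, m_B_to_dip = 0,
                                n_disomic_loci = 0L, generation_time = 2) {
  p <- list(N_dip = N_dip, N_ext = N_ext, N_tet = N_tet, N_anc = N_anc,
            T_split = T_split, T_WGD = T_WGD,
            m_dip_to_A = m_dip_to_A, m_dip_to_B = m_dip_to_B,
            m_A_to_dip = m_A_to_dip, m_B_to_dip = m_B_to_dip,
            n_disomic_loci = as.integer(n_disomic_loci),
            generation_time = generation_time)
  if (any(unlist(p[c("N_dip", "N_ext", "N_tet", "N_anc")]) <= 0))
    stop("deme sizes must be positive")
  if (p$T_WGD < 0 || p$T_split < 0 || p$T_WGD > p$T_split)
    stop("times must satisfy 0 <= T_WGD <= T_split")
  m <- unlist(p[c("m_dip_to_A", "m_dip_to_B", "m_A_to_dip", "m_B_to_dip")])
  if (any(m < 0 | m >= 0.5))
    stop("migrant fractions must lie in [0, 0.5)")
  if (p$generation_time <= 0) stop("generation_time must be positive")
  structure(p, class = "scenario_parameters")
}

check_scenario_params <- function(scenario, params) {
  if (scenario$inheritance == "tetrasomic" && params$n_disomic_loci != 0L)
    stop("tetrasomic inheritance implies n_disomic_loci = 0")
  m <- scenario$migration
  act <- c(A = params$m_dip_to_A > 0, B = params$m_dip_to_B > 0,
           Ad = params$m_A_to_dip > 0, Bd = params$m_B_to_dip > 0)
  bad <- switch(m,
    none = any(act),
    unidirectional_dip_to_AB = any(act[c("Ad", "Bd")]),
    unidirectional_dip_to_A = any(act[c("B", "Ad", "Bd")]),
    unidirectional_dip_to_B = any(act[c("A", "Ad", "Bd")]),
    bidirectional_AB = FALSE)
  if (bad)
    stop("migration parameters inconsistent with scenario '", m, "'")
  invisible(TRUE)
}

#' Uniform prior set for scenario parameters
#'
#' Finite uniform bounds per parameter, with the joint constraint
#' `T_WGD <= T_split` enforced at draw time (the WGD time is drawn uniformly
#' between its lower bound and the drawn split time). Defaults span the
#' plausible late-Pleistocene history of a recent anuran polyploid and
#' contain the posterior intervals such an analysis reports.
#'
#' @param N_bounds Bounds for every deme size (gene copies).
#' @param T_split_bounds,T_WGD_bounds Bounds in years.
#' @param m_bounds Bounds for per-generation migrant fractions.
#' @return An object of class `prior_set`: named list of `c(lo, hi)` bounds.
#' @export
prior_set <- function(N_bounds = c(1e3, 1e6),
                      T_split_bounds = c(1e3, 1e7),
                      T_WGD_bounds = c(1e2, 1e7),
                      m_bounds = c(0, 1e-3)) {
  chk <- function(b, nm) {
    if (length(b) != 2L || any(!is.finite(b)) || b[1L] >= b[2L])
      stop("invalid bounds for ", nm)
    b
  }
  structure(list(
    N_dip = chk(N_bounds, "N"), N_ext = chk(N_bounds, "N"),
    N_tet = chk(N_bounds, "N"), N_anc = chk(N_bounds, "N"),
    T_split = chk(T_split_bounds, "T_split"),
    T_WGD = chk(T_WGD_bounds, "T_WGD"),
    m = chk(m_bounds, "m")), class = "prior_set")
}

#' Draw scenario parameters from their priors
#'
#' Independent uniform draws for deme sizes, split time, and the migration
#' fractions the scenario's migration pattern opens (closed routes are fixed
#' at zero); `T_WGD` is drawn uniformly on (lower bound, drawn `T_split`) so
#' the joint order constraint always holds.
#'
#' @param priors A [prior_set()].
#' @param scenario A [polyploid_scenario()].
#' @param generation_time Years per generation (not a prior).
#' @param n_loci Needed for heterosomic scenarios: `n_disomic_loci` is drawn
#'   discrete-uniform on 0..`n_loci`.
#' @return A [scenario_parameters()] draw.
#' @export
sample_prior <- function(priors, scenario = polyploid_scenario(),
                         generation_time = 2, n_loci = 50L) {
  u <- function(b) stats::runif(1L, b[1L], b[2L])
  T_split <- u(priors$T_split)
  lo_wgd <- min(priors$T_WGD[1L], T_split)
  T_WGD <- stats::runif(1L, lo_wgd, min(priors$T_WGD[2L], T_split))
  mdraw <- function() u(priors$m)
  mA <- mB <- mAd <- mBd <- 0
  if (scenario$migration %in% c("unidirectional_dip_to_AB", "bidirectional_AB")) {
    mA <- mdraw(); mB <- mdraw()
  }
  if (scenario$migration == "unidirectional_dip_to_A") mA <- mdraw()
  if (scenario$migration == "unidirectional_dip_to_B") mB <- mdraw()
  if (scenario$migration == "bidirectional_AB") { mAd <- mdraw(); mBd <- mdraw() }
  n_dis <- if (scenario$inheritance == "heterosomic")
    sample.int(n_loci + 1L, 1L) - 1L else 0L
  scenario_parameters(
    N_dip = u(priors$N_dip), N_ext = u(priors$N_ext),
    N_tet = u(priors$N_tet), N_anc = u(priors$N_anc),
    T_split = T_split, T_WGD = T_WGD,
    m_dip_to_A = mA, m_dip_to_B = mB,
    m_A_to_dip = mAd, m_B_to_dip = mBd,
    n_disomic_loci = n_dis, generation_time = generation_time)
}
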