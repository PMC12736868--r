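#' Vacuum permittivity (F/m)
#'
#' Fixed physical constant used throughout the dielectric conversions.
#' @export
EPS0 <- 8.8541878128e-12

#' Construct a tissue dielectric parameter set
#'
#' A 4-term Cole-Cole dispersion model plus a static ionic conductivity:
#' \deqn{\hat\varepsilon(\omega) = \varepsilon_\infty +
#'   \sum_{n=1}^{4} \frac{\Delta\varepsilon_n}{1 + (j\omega\tau_n)^{1-\alpha_n}} +
#'   \frac{\sigma_s}{j\omega\varepsilon_0}}
#'
#' @param name tissue label.
#' @param eps_inf relative permittivity at infinite frequency (>= 1).
#' @param delta_eps numeric vector (up to 4) of dispersion magnitudes.
#' @param tau numeric vector of relaxation time constants in seconds (> 0).
#' @param alpha numeric vector of broadening exponents in [0, 1).
#' @param sigma_static static ionic conductivity in S/m (>= 0).
#' @param source free-text provenance note.
#' @return object of class `tissue_dielectric`.
#' @export
tissue_dielectric <- function(name, eps_inf, delta_eps, tau, alpha,
                              sigma_static, source = "") {
  stopifnot(length(delta_eps) == length(tau),
            length(tau) == length(alpha),
            length(delta_eps) <= 4)
  if (eps_inf < 1) stop("eps_inf must be >= 1")
  if (any(tau <= 0)) stop("all tau must be > 0")
  if (any(alpha < 0 | alpha >= 1)) stop("alpha must lie in [0, 1)")
  if (sigma_static < 0) stop("sigma_static must be >= 0")
  structure(list(name = name, eps_inf = eps_inf, delta_eps = delta_eps,
                 tau = tau, alpha = alpha, sigma_static = sigma_static,
                 source = source),
            class = "tissue_dielectric")
}

#' @export
print.tissue_dielectric <- function(x, ...) {
  cat(sprintf("<tissue_dielectric: %s>\n", x$name))
  cat(sprintf("  eps_inf = %g, sigma_static = %g S/m, %d dispersion term(s)\n",
              x$eps_inf, x$sigma_static, sum(x$delta_eps != 0)))
  invisible(x)
}

#' Complex relative permittivity of a tissue at a frequency
#'
#' Evaluates the Cole-Cole model of [tissue_dielectric()] at a single
#' frequency. For a lossy tissue the imaginary part is negative.
#'
#' @param tissue a `tissue_dielectric`.
#' @param frequency frequency in Hz (> 0). May be a vector.
#' @return complex relative permittivity (same length as `frequency`).
#' @export
cole_cole_complex_permittivity <- function(tissue, frequency) {
  stopifnot(inherits(tissue, "tissue_dielectric"))
  if (any(frequency <= 0)) stop("frequency must be > 0")
  w <- 2 * pi * frequency
  eps <- complex(real = rep(tissue$eps_inf, length(w)), imaginary = 0)
  for (n in seq_along(tissue$delta_eps)) {
    if (tissue$delta_eps[n] == 0) next
    expo <- 1 - tissue$alpha[n]
    # (j w tau)^(1-alpha) for w > 0: magnitude (w tau)^(1-alpha), phase (1-alpha) pi/2
    jwt <- complex(modulus = (w * tissue$tau[n])^expo,
                   argument = expo * pi / 2)
    eps <- eps + tissue$delta_eps[n] / (1 + jwt)
  }
  eps + tissue$sigma_static / (1i * w * EPS0)
}

#' Effective conductivity and relative permittivity
#'
#' Converts the complex relative permittivity into the (sigma, eps_r) pair the
#' forward solver consumes, via sigma* = j w eps0 eps-hat:
#' sigma = -w eps0 Im(eps-hat), eps_r = Re(eps-hat).
#'
#' @inheritParams cole_cole_complex_permittivity
#' @return list with `conductivity` (S/m) and `relative_permittivity`.
#' @export
effective_properties <- function(tissue, frequency) {
  eps <- cole_cole_complex_permittivity(tissue, frequency)
  w <- 2 * pi * frequency
  list(conductivity = -w * EPS0 * Im(eps),
       relative_permittivity = Re(eps))
}

#' Complex conductivity sigma* = sigma + j w eps0 eps_r
#'
#' @inheritParams cole_cole_complex_permittivity
#' @return complex conductivity in S/m.
#' @export
complex_conductivity <- function(tissue, frequency) {
  p <- effective_properties(tissue, frequency)
  complex(real = p$conductivity,
          imaginary = 2 * pi * frequency * EPS0 * p$relative_permittivity)
}

#' Shipped tissue dielectric parameter table
#'
#' Returns the dielectric parameter set for one of the five simulation
#' domains. Values are shipped as an editable flat table
#' (`inst/extdata/tissue_dielectrics.tsv`); pass `file` to substitute a
#' user-supplied table with the same columns. The urine set is a literature
#' default (saline-like electrolyte), and the gel is a constant-property
#' fallback standing in for a digitized interpolation curve.
#'
#' @param name one of `"bladder_urine"`, `"electrode_gel"`,
#'   `"fat_infiltrated"`, `"muscle"`, `"skin_dry"`.
#' @param file optional path to an alternative parameter table.
#' @return a `tissue_dielectric`.
#' @export
tissue_table <- function(name, file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "tissue_dielectrics.tsv",
                        package = "bladdersim", mustWork = TRUE)
  }
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!name %in% tab$name) {
    stop(sprintf("unknown tissue '%s'; valid names: %s",
                 name, paste(sort(tab$name), collapse = ", ")))
  }
  row <- tab[tab$name == name, , drop = FALSE]
  tissue_dielectric(
    name = name,
    eps_inf = row$eps_inf,
    delta_eps = as.numeric(row[paste0("deps", 1:4)]),
    tau = as.numeric(row[paste0("tau", 1:4)]),
    alpha = as.numeric(row[paste0("alpha", 1:4)]),
    sigma_static = row$sigma_static,
    source = row$source
  )
}
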