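#' Cell-level model constants
#'
#' Bundles the whole-cell parameters shared by every gene. Units are minutes,
#' cubic micrometres and amino-acid (codon) counts throughout.
#'
#' The defaults encode the stated simulation world: an attempted growth rate
#' `mu0 = 0.006`/min together with `v_r = 600` codons/min and a ribosome gene
#' of 10^4 codons gives an attempted ribosome mass fraction of 0.1, an
#' attempted RNAP count of 10^3 (10% of the ribosome count), and therefore an
#' initial RNAP saturation `n(0)/n_c = 0.1` that reaches 0.9 when the total
#' protein mass has grown 9-fold. The protein density `rho` and the
#' cell-to-nuclear volume ratio `a` are coarse-graining scales chosen so that
#' the total nuclear RNAP concentration (`c_n = 0.1 mu0 rho a / v_r`, constant
#' in Phase 1) is several hundred times the typical Michaelis-Menten constant
#' of 6e3 molecules/um^3 - the model's assumption `c_n >> K_n`, which keeps
#' the free-RNAP fraction below ~2% over the whole simulated range. Only the
#' ratio `c_n / K_n` enters the dynamics.
#'
#' @param v_n RNAP elongation speed, codons/min.
#' @param v_r ribosome elongation speed, codons/min.
#' @param rho protein mass per cell volume, amino acids/um^3.
#' @param a ratio of cell volume to nuclear volume (> 1).
#' @param mu0 attempted growth rate, 1/min.
#' @param M_b attempted initial total protein mass, amino acids.
#' @param n_c_target attempted critical RNAP number
#'   \eqn{n_c = \sum_i g_i (1 + \Lambda_{n,i})}.
#' @return An object of class `volscale_globals` (a named list).
#' @examples
#' gl <- global_params()
#' gl$mu0 * 1e4 / gl$v_r   # attempted ribosome mass fraction for L_r = 1e4
#' @export
global_params <- function(v_n = 2400, v_r = 600, rho = 3e11, a = 10,
                          mu0 = 0.006, M_b = 1e9, n_c_target = 1e4) {
  gl <- list(v_n = v_n, v_r = v_r, rho = rho, a = a, mu0 = mu0,
             M_b = M_b, n_c_target = n_c_target)
  for (nm in names(gl)) {
    v <- gl[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("global parameter '", nm, "' must be a single positive finite number")
  }
  if (a <= 1) stop("'a' (cell volume / nuclear volume) must exceed 1")
  structure(gl, class = "volscale_globals")
}

#' @export
print.volscale_globals <- function(x, ...) {
  cat("volscale global parameters\n")
  cat(sprintf("  elongation speeds   v_n = %g, v_r = %g codons/min\n", x$v_n, x$v_r))
  cat(sprintf("  protein density     rho = %g aa/um^3\n", x$rho))
  cat(sprintf("  V/V_nucleus         a   = %g\n", x$a))
  cat(sprintf("  attempted growth    mu0 = %g /min\n", x$mu0))
  cat(sprintf("  attempted mass      M_b = %g aa\n", x$M_b))
  cat(sprintf("  attempted n_c       %g\n", x$n_c_target))
  invisible(x)
}

as_globals <- function(x) {
  if (inherits(x, "volscale_globals")) return(x)
  if (is.list(x)) return(do.call(global_params, x))
  stop("cannot interpret 'globals'; use global_params()")
}
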