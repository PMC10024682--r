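#' Specify a disordered peptide linker
#'
#' A `linker_spec` describes an unstructured peptide span as a polymer:
#' the number of residues, the contour length contributed by each residue,
#' and (for the worm-like chain) the persistence length.
#'
#' @param n_residues Integer, number of residues in the span (>= 2). A span
#'   of `n` residues has `n - 1` backbone steps.
#' @param step_length_nm Contour length per residue in nm. Default 0.37 nm,
#'   the standard per-residue backbone length of an extended peptide.
#' @param persistence_nm Persistence length in nm (worm-like chain stiffness).
#'   Disordered peptides fall around 0.3--0.7 nm.
#' @return An object of class `linker_spec`.
#' @examples
#' linker_spec(107)                      # e.g. CDC20 residues 27-133
#' linker_spec(50, persistence_nm = 0.5)
#' @export
linker_spec <- function(n_residues, step_length_nm = 0.37, persistence_nm = 0.5) {
  if (!is.numeric(n_residues) || length(n_residues) != 1L ||
      n_residues != round(n_residues) || n_residues < 2)
    stop("linker_spec: 'n_residues' must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(step_length_nm) || length(step_length_nm) != 1L || step_length_nm <= 0)
    stop("linker_spec: 'step_length_nm' must be a single positive number", call. = FALSE)
  if (!is.numeric(persistence_nm) || length(persistence_nm) != 1L || persistence_nm <= 0)
    stop("linker_spec: 'persistence_nm' must be a single positive number", call. = FALSE)
  structure(
    list(n_residues = as.integer(n_residues),
         step_length_nm = step_length_nm,
         persistence_nm = persistence_nm),
    class = "linker_spec"
  )
}

#' @export
print.linker_spec <- function(x, ...) {
  cat(sprintf("<linker_spec> n = %d residues, r = %.3g nm/residue, p = %.3g nm (L = %.4g nm)\n",
              x$n_residues, x$step_length_nm, x$persistence_nm, contour_length(x)))
  invisible(x)
}

as_linker_spec <- function(spec) {
  if (!inherits(spec, "linker_spec"))
    stop("expected a 'linker_spec' object; see linker_spec()", call. = FALSE)
  spec
}

chain_estimate <- function(model, rmsd_nm, contour_length_nm,
                           mc_stderr_nm = NA_real_, n_chains = NA_integer_) {
  structure(
    list(model = model, rmsd_nm = rmsd_nm, contour_length_nm = contour_length_nm,
         mc_stderr_nm = mc_stderr_nm, n_chains = n_chains),
    class = "chain_estimate"
  )
}

#' @export
print.chain_estimate <- function(x, ...) {
  cat(sprintf("<chain_estimate> model = %s, RMSD = %.4g nm (contour %.4g nm)",
              x$model, x$rmsd_nm, x$contour_length_nm))
  if (!is.na(x$mc_stderr_nm))
    cat(sprintf(" +/- %.3g nm SE, %d chains", x$mc_stderr_nm, x$n_chains))
  cat("\n")
  invisible(x)
}

#' Contour length of a peptide linker
#'
#' `L = (n - 1) * r`: the fully extended length of the span.
#'
#' @param spec A [linker_spec()].
#' @return Contour length in nm.
#' @examples
#' contour_length(linker_spec(107))  # 106 * 0.37 = 39.22 nm
#' @export
contour_length <- function(spec) {
  spec <- as_linker_spec(spec)
  (spec$n_residues - 1) * spec$step_length_nm
}

#' Ideal-chain (3-D random walk) end-to-end RMS distance
#'
#' Models the peptide as `n - 1` independent, isotropic steps of fixed
#' length `r`. Cross terms between steps vanish in expectation, so the
#' root-mean-square end-to-end distance is `r * sqrt(n - 1) = L / sqrt(n - 1)`.
#'
#' @param spec A [linker_spec()].
#' @return A `chain_estimate` with `model = "random_walk"`.
#' @examples
#' random_walk_rmsd(linker_spec(107))  # about 3.81 nm
#' @export
random_walk_rmsd <- function(spec) {
  spec <- as_linker_spec(spec)
  n_steps <- spec$n_residues - 1L
  chain_estimate("random_walk",
                 rmsd_nm = spec$step_length_nm * sqrt(n_steps),
                 contour_length_nm = contour_length(spec))
}

#' Worm-like chain end-to-end RMS distance
#'
#' Treats the peptide as a continuous chain with bending stiffness set by
#' the persistence length `p`:
#' `RMSD = sqrt(2 p L (1 - (p/L) (1 - exp(-L/p))))` with contour length `L`.
#' In the stiff limit `L/p -> 0` this tends to the rigid rod `L`; in the
#' flexible limit `L/p -> Inf` it tends to `sqrt(2 p L)`.
#'
#' The bracket is evaluated with `expm1` to avoid catastrophic cancellation
#' when `L/p` is small.
#'
#' @param spec A [linker_spec()]; `persistence_nm` is used.
#' @return A `chain_estimate` with `model = "wlc"`.
#' @examples
#' wlc_rmsd(linker_spec(107, persistence_nm = 0.3))  # about 4.83 nm
#' wlc_rmsd(linker_spec(107, persistence_nm = 0.7))  # about 7.34 nm
#' @export
wlc_rmsd <- function(spec) {
  spec <- as_linker_spec(spec)
  L <- contour_length(spec)
  p <- spec$persistence_nm
  # 1 - (p/L)(1 - e^(-L/p)) == 1 + (p/L) expm1(-L/p), kept in expm1 form
  bracket <- 1 + (p / L) * expm1(-L / p)
  chain_estimate("wlc",
                 rmsd_nm = sqrt(2 * p * L * bracket),
                 contour_length_nm = L)
}

#' Monte-Carlo ideal-chain end-to-end RMS distance
#'
#' Simulates `n_chains` independent 3-D walks of `n - 1` unit-length steps
#' drawn isotropically on the sphere (no excluded volume), rescales by the
#' per-residue step length, and returns `sqrt(mean(|D|^2))` with a
#' delta-method standard error. Serves as a stochastic check on the
#' closed-form ideal-chain result.
#'
#' @param spec A [linker_spec()].
#' @param n_chains Number of simulated chains (>= 1).
#' @param seed Integer seed; the estimate is reproducible for a fixed seed.
#' @return A `chain_estimate` with `model = "monte_carlo"`, `mc_stderr_nm`
#'   and `n_chains` filled in.
#' @examples
#' mc_random_walk_rmsd(linker_spec(107), n_chains = 1e4, seed = 1)
#' @export
mc_random_walk_rmsd <- function(spec, n_chains, seed = 1L) {
  spec <- as_linker_spec(spec)
  if (!is.numeric(n_chains) || length(n_chains) != 1L || n_chains < 1)
    stop("mc_random_walk_rmsd: 'n_chains' must be >= 1", call. = FALSE)
  n_chains <- as.integer(n_chains)
  n_steps <- spec$n_residues - 1L

  d2 <- numeric(n_chains)
  chunk <- 5000L
  done <- 0L
  # local RNG so callers' random state is untouched
  withr_seed <- local_seed(seed)
  on.exit(withr_seed(), add = TRUE)
  while (done < n_chains) {
    m <- min(chunk, n_chains - done)
    # isotropic unit steps: cos(theta) ~ U(-1,1), phi ~ U(0, 2pi)
    z <- matrix(stats::runif(n_steps * m, -1, 1), n_steps, m)
    phi <- matrix(stats::runif(n_steps * m, 0, 2 * pi), n_steps, m)
    s <- sqrt(pmax(0, 1 - z^2))
    dx <- .colSums(s * cos(phi), n_steps, m)
    dy <- .colSums(s * sin(phi), n_steps, m)
    dz <- .colSums(z, n_steps, m)
    d2[(done + 1L):(done + m)] <- dx^2 + dy^2 + dz^2
    done <- done + m
  }
  d2 <- d2 * spec$step_length_nm^2
  rmsd <- sqrt(mean(d2))
  se <- if (n_chains > 1L) stats::sd(d2) / sqrt(n_chains) / (2 * rmsd) else 0
  chain_estimate("monte_carlo", rmsd_nm = rmsd,
                 contour_length_nm = contour_length(spec),
                 mc_stderr_nm = se, n_chains = n_chains)
}

# Set the RNG to `seed`, returning a restorer for the previous state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
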