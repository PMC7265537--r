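# The proteomic constraint on mutation rate.
#
# Under the proteomic-constraint view, the amount of coding information in
# a genome (approximated by proteome size P, in amino acids) sets the size
# of the mutational target, and the sustainable mutation rate mu scales as
#
#   mu = k / (2 * Ne * s_bar * pi * P)
#
# where Ne is the effective population size, s_bar the mean (deleterious)
# selection coefficient of a mutation, pi the genomic heterozygosity per
# bp, and k a dimensionless proportionality constant (no calibrated
# default exists). Because pi tends to fall and s_bar to rise with Ne,
# those two factors tend to cancel, leaving P as the lever: a smaller
# proteome tolerates a higher mutation rate, relaxing selection on DNA
# repair.

CONSTRAINT_PARAMS <- c("k", "ne", "s_bar", "pi", "p")

#' Mutation rate under the proteomic constraint
#'
#' @param k proportionality constant (dimensionless, > 0)
#' @param ne effective population size (individuals, > 0)
#' @param s_bar mean deleterious selection coefficient (> 0)
#' @param pi genomic heterozygosity per bp (> 0)
#' @param p proteome size in amino acids (> 0)
#' @return mu, mutations per nucleotide per generation
#' @export
mutation_rate <- function(k, ne, s_bar, pi, p) {
  vals <- c(k = k, ne = ne, s_bar = s_bar, pi = pi, p = p)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_invalid("all parameters must be finite and strictly positive")
  }
  k / (2 * ne * s_bar * pi * p)
}

#' Solve the proteomic-constraint relation for one parameter
#'
#' Given the mutation rate and all but one of the remaining parameters,
#' returns the value of the missing one. Substituting the solution back
#' into [mutation_rate()] reproduces `mu` exactly (to floating point).
#'
#' @param target one of `"k"`, `"ne"`, `"s_bar"`, `"pi"`, `"p"`
#' @param mu mutation rate (> 0)
#' @param k,ne,s_bar,pi,p the known parameters (the target may be omitted)
#' @return the solved parameter value
#' @export
solve_constraint <- function(target, mu, k = NULL, ne = NULL, s_bar = NULL,
                             pi = NULL, p = NULL) {
  target <- match.arg(target, CONSTRAINT_PARAMS)
  known <- list(k = k, ne = ne, s_bar = s_bar, pi = pi, p = p)
  needed <- setdiff(CONSTRAINT_PARAMS, target)
  vals <- unlist(known[needed])
  if (length(vals) != length(needed) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop_invalid("all non-target parameters must be supplied, finite and positive")
  }
  if (!is.finite(mu) || mu <= 0) stop_invalid("mu must be finite and positive")
  if (target == "k") {
    2 * mu * prod(vals)          # vals = ne, s_bar, pi, p
  } else {
    known$k[[1]] / (2 * mu * prod(unlist(known[setdiff(needed, "k")])))
  }
}
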