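#' @importFrom stats median prcomp quantile rnorm runif sd setNames approx
#' @importFrom utils head tail write.csv read.csv
NULL

# Species table for the p53-Mdm2-MdmX network.
# Subunit weights count protein copies per complex (p53P dimer carries 2 p53
# subunits, the tetramer and the tetramer:promoter complex carry 4).
.species_table <- data.frame(
  index = 1:16,
  name  = c("p53", "p53P", "Mdm2", "Mdm2P", "MdmX", "MdmXP",
            "p53:Mdm2", "Mdm2:MdmXP", "Mdm2:MdmX", "p53:MdmX",
            "p53P_dimer", "p53P_tetramer", "promoter",
            "tetramer:promoter", "mRNA", "p53:promoter"),
  p53_subunits = c(1, 1, 0, 0, 0, 0, 1, 0, 0, 1, 2, 4, 0, 4, 0, 1),
  mdm2_units   = c(0, 0, 1, 1, 0, 0, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
  mdmx_units   = c(0, 0, 0, 0, 1, 1, 0, 1, 1, 1, 0, 0, 0, 0, 0, 0),
  stringsAsFactors = FALSE
)

# Reaction list. Each row: reactant/product species indices (0 = none) and
# the rate-constant symbol. Bimolecular self-reactions (p53P dimerization,
# dimer-of-dimers) repeat the index; their flux is k * x^2.
# The symbol "k33" is variant-scoped: in the simple model it drives reaction
# 33 (promoter complex directly produces Mdm2), in the full model reaction 34
# (promoter complex produces mRNA). Rows 35-39 map to symbols k37, k38, k34,
# k35, k36 in that order.
.reaction_table <- list(
  list(id = 1L,  re = integer(0),  pr = 1L,        sym = "k1",  scope = "both"),
  list(id = 2L,  re = 1L,          pr = integer(0), sym = "k2", scope = "both"),
  list(id = 3L,  re = 1L,          pr = 2L,        sym = "k3",  scope = "both"),
  list(id = 4L,  re = 2L,          pr = 1L,        sym = "k4",  scope = "both"),
  list(id = 5L,  re = 2L,          pr = integer(0), sym = "k5", scope = "both"),
  list(id = 6L,  re = integer(0),  pr = 3L,        sym = "k6",  scope = "both"),
  list(id = 7L,  re = 3L,          pr = integer(0), sym = "k7", scope = "both"),
  list(id = 8L,  re = 3L,          pr = 4L,        sym = "k8",  scope = "both"),
  list(id = 9L,  re = 4L,          pr = 3L,        sym = "k9",  scope = "both"),
  list(id = 10L, re = 4L,          pr = integer(0), sym = "k10", scope = "both"),
  list(id = 11L, re = c(1L, 3L),   pr = 7L,        sym = "k11", scope = "both"),
  list(id = 12L, re = 7L,          pr = c(1L, 3L), sym = "k12", scope = "both"),
  list(id = 13L, re = 7L,          pr = 3L,        sym = "k13", scope = "both"),
  list(id = 14L, re = 7L,          pr = 1L,        sym = "k14", scope = "both"),
  list(id = 15L, re = integer(0),  pr = 5L,        sym = "k15", scope = "both"),
  list(id = 16L, re = 5L,          pr = integer(0), sym = "k16", scope = "both"),
  list(id = 17L, re = 5L,          pr = 6L,        sym = "k17", scope = "both"),
  list(id = 18L, re = 6L,          pr = 5L,        sym = "k18", scope = "both"),
  list(id = 19L, re = 6L,          pr = integer(0), sym = "k19", scope = "both"),
  list(id = 20L, re = c(3L, 6L),   pr = 8L,        sym = "k20", scope = "both"),
  list(id = 21L, re = 8L,          pr = c(3L, 6L), sym = "k21", scope = "both"),
  list(id = 22L, re = 8L,          pr = 3L,        sym = "k22", scope = "both"),
  list(id = 23L, re = c(3L, 5L),   pr = 9L,        sym = "k23", scope = "both"),
  list(id = 24L, re = 9L,          pr = c(3L, 5L), sym = "k24", scope = "both"),
  list(id = 25L, re = c(1L, 5L),   pr = 10L,       sym = "k25", scope = "both"),
  list(id = 26L, re = 10L,         pr = c(1L, 5L), sym = "k26", scope = "both"),
  list(id = 27L, re = c(2L, 2L),   pr = 11L,       sym = "k27", scope = "both"),
  list(id = 28L, re = 11L,         pr = c(2L, 2L), sym = "k28", scope = "both"),
  list(id = 29L, re = c(11L, 11L), pr = 12L,       sym = "k29", scope = "both"),
  list(id = 30L, re = 12L,         pr = c(11L, 11L), sym = "k30", scope = "both"),
  list(id = 31L, re = c(12L, 13L), pr = 14L,       sym = "k31", scope = "both"),
  list(id = 32L, re = 14L,         pr = c(12L, 13L), sym = "k32", scope = "both"),
  list(id = 33L, re = 14L,         pr = c(3L, 14L), sym = "k33", scope = "simple"),
  list(id = 34L, re = 14L,         pr = c(14L, 15L), sym = "k33", scope = "full"),
  list(id = 35L, re = 15L,         pr = integer(0), sym = "k37", scope = "full"),
  list(id = 36L, re = 15L,         pr = c(3L, 15L), sym = "k38", scope = "full"),
  list(id = 37L, re = c(1L, 13L),  pr = 16L,       sym = "k34", scope = "full"),
  list(id = 38L, re = 16L,         pr = c(1L, 13L), sym = "k35", scope = "full"),
  list(id = 39L, re = 16L,         pr = c(15L, 16L), sym = "k36", scope = "full")
)

.k_symbols <- paste0("k", 1:38)

#' Build a p53-Mdm2-MdmX reaction network
#'
#' Assembles the mass-action reaction system in one of two variants. The
#' simple variant has 14 species (no mRNA, no p53:promoter complex) and 33
#' reactions, with the promoter-bound p53 tetramer producing Mdm2 directly.
#' The full variant has 16 species and 38 reactions: the promoter complex
#' produces mRNA which in turn produces Mdm2, and unphosphorylated p53 can
#' bind the promoter to drive basal transcription.
#'
#' @param variant `"simple"` or `"full"`.
#' @param delay_on if `TRUE` (simple variant only), the Mdm2-production
#'   reaction driven by the promoter complex acts with a time delay of
#'   `delay` time units on its rate-determining species.
#' @param delay delay duration in model time units (default 50).
#' @return An object of class `reaction_network` with the species table,
#'   reaction list, stoichiometry matrix and precomputed flux indices.
#' @export
build_network <- function(variant = c("simple", "full"), delay_on = FALSE,
                          delay = 50) {
  variant <- match.arg(variant)
  if (delay_on && variant == "full")
    stop("the delayed Mdm2-production reaction exists only in the simple variant")
  keep <- vapply(.reaction_table, function(r)
    r$scope == "both" || r$scope == variant, logical(1))
  reactions <- .reaction_table[keep]
  n_sp <- if (variant == "simple") 14L else 16L
  species <- .species_table[seq_len(n_sp), ]

  S <- matrix(0L, nrow = n_sp, ncol = length(reactions))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    for (i in r$re) S[i, j] <- S[i, j] - 1L
    for (i in r$pr) S[i, j] <- S[i, j] + 1L
  }
  rownames(S) <- paste0("x", seq_len(n_sp))
  colnames(S) <- vapply(reactions, function(r) as.character(r$id), "")

  # flux index vectors: ra/rb are first/second reactant (NA if absent)
  ra <- vapply(reactions, function(r) if (length(r$re) >= 1) r$re[1] else NA_integer_, 1L)
  rb <- vapply(reactions, function(r) if (length(r$re) >= 2) r$re[2] else NA_integer_, 1L)
  sym <- vapply(reactions, function(r) r$sym, "")
  delays <- rep(0, length(reactions))
  if (delay_on) {
    if (delay < 0) stop("delay must be nonnegative")
    delays[vapply(reactions, function(r) r$id == 33L, logical(1))] <- delay
  }

  structure(list(
    variant = variant, species = species, reactions = reactions,
    stoichiometry = S, ra = ra, rb = rb, rate_symbol = sym,
    k_index = match(sym, .k_symbols), delays = delays,
    n_species = n_sp, n_reactions = length(reactions)
  ), class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %s variant: %d species, %d reactions%s\n",
              x$variant, x$n_species, x$n_reactions,
              if (any(x$delays > 0))
                sprintf(" (delay %g on Mdm2 production)", max(x$delays)) else ""))
  invisible(x)
}

#' Mass-action reaction fluxes
#'
#' @param state nonnegative species concentration vector.
#' @param k named rate-constant vector (`k1`..`k38`).
#' @param network a [build_network()] object.
#' @return flux per reaction (homodimerization fluxes are `k * x^2`).
#' @export
reaction_flux <- function(state, k, network) {
  v <- k[network$k_index]
  i1 <- !is.na(network$ra)
  v[i1] <- v[i1] * state[network$ra[i1]]
  i2 <- !is.na(network$rb)
  v[i2] <- v[i2] * state[network$rb[i2]]
  unname(v)
}

#' Mass-action right-hand side
#'
#' Time derivative of the species concentrations: stoichiometry matrix times
#' the reaction flux vector.
#'
#' @inheritParams reaction_flux
#' @return derivative vector of length `network$n_species`.
#' @export
network_rhs <- function(state, k, network) {
  drop(network$stoichiometry %*% reaction_flux(state, k, network))
}

#' Analytic Jacobian of the mass-action right-hand side
#'
#' @inheritParams reaction_flux
#' @return `n_species x n_species` matrix of partial derivatives.
#' @export
network_jacobian <- function(state, k, network) {
  n <- network$n_species
  m <- network$n_reactions
  D <- matrix(0, m, n)
  kk <- k[network$k_index]
  for (j in seq_len(m)) {
    a <- network$ra[j]; b <- network$rb[j]
    if (is.na(a)) next
    if (is.na(b)) {
      D[j, a] <- kk[j]
    } else if (a == b) {
      D[j, a] <- 2 * kk[j] * state[a]
    } else {
      D[j, a] <- kk[j] * state[b]
      D[j, b] <- kk[j] * state[a]
    }
  }
  network$stoichiometry %*% D
}

# Promoter-moiety species indices present in a network (x13, x14 and, in the
# full variant, x16). Their total is conserved by every reaction.
promoter_species <- function(network) {
  idx <- c(13L, 14L, if (network$variant == "full") 16L)
  idx[idx <= network$n_species]
}
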