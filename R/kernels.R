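#' Generate the antisymmetric trait-pair score matrix
#'
#' Draws the strict upper triangle from Uniform(0, 1) and mirrors it with
#' negated sign, so that \eqn{\beta_{a,b} = -\beta_{b,a}} and the diagonal
#' is exactly zero. The antisymmetry is what makes a species' feeding score
#' on itself vanish and gives a random consumer probability exactly 1/2 of
#' a positive trait-pair sum against a random prey.
#'
#' @param pool_size Number of traits in the pool (matrix dimension).
#' @return A \code{pool_size x pool_size} numeric matrix.
#' @export
#' @examples
#' set.seed(1)
#' b <- generate_score_matrix(10)
#' max(abs(b + t(b)))  # 0
generate_score_matrix <- function(pool_size) {
  pool_size <- as.integer(pool_size)
  if (is.na(pool_size) || pool_size < 2L)
    stop("pool_size must be at least 2", call. = FALSE)
  m <- matrix(0, pool_size, pool_size)
  ut <- upper.tri(m)
  m[ut] <- stats::runif(sum(ut))
  m - t(m)
}

#' Construct a species
#'
#' A species is a set of distinct discrete traits plus one continuous
#' bodysize. Resources are non-evolving basal species of bodysize 1 that
#' never act as consumers.
#'
#' @param traits Integer vector of distinct trait labels.
#' @param bodysize Positive bodysize.
#' @param id Optional stable integer identity.
#' @param is_resource Logical resource flag.
#' @param parent_id Optional lineage reference.
#' @param birth_step Evolutionary step at which the species arose.
#' @return An object of class \code{"mc_species"}.
#' @export
species <- function(traits, bodysize, id = NA_integer_, is_resource = FALSE,
                    parent_id = NA_integer_, birth_step = NA_integer_) {
  traits <- as.integer(traits)
  if (anyDuplicated(traits)) stop("species traits must be distinct", call. = FALSE)
  if (!is.numeric(bodysize) || length(bodysize) != 1L || bodysize <= 0)
    stop("bodysize must be a positive scalar", call. = FALSE)
  structure(list(id = as.integer(id), traits = traits, bodysize = bodysize,
                 is_resource = isTRUE(is_resource),
                 parent_id = as.integer(parent_id),
                 birth_step = as.integer(birth_step)),
            class = "mc_species")
}

#' Number of traits shared by two species
#'
#' @param i,k Species (see \code{\link{species}}).
#' @return Integer count in 0..traits-per-species; symmetric in its
#'   arguments.
#' @export
shared_traits <- function(i, k) {
  length(intersect(i$traits, k$traits))
}

# trait-pair sum sum_{m,n} beta[i_m, j_n]; antisymmetric in (i, j)
trait_pair_sum <- function(traits_i, traits_j, beta) {
  sum(beta[traits_i, traits_j])
}

#' Feeding score of a consumer on a prey species
#'
#' \deqn{S_{i,j} = \max(0, \sum_{m,n} \beta_{i_m, j_n}) \cdot b_1
#'   \exp(-(\ln s_i - \ln s_j - 3)^2 / b_2)}
#'
#' The max(0, .) clips only the trait-pair sum; the Gaussian bodysize window
#' (optimal prey three log-units smaller than the consumer) multiplies the
#' clipped sum, so a trait combination that confers no advantage scores 0
#' regardless of bodysizes.
#'
#' @param i Consumer species; must not be a resource.
#' @param j Prey species.
#' @param beta Score matrix from \code{\link{generate_score_matrix}}.
#' @param params \code{\link{model_params}}.
#' @return Non-negative feeding score; 0 for a species on itself.
#' @export
feeding_score <- function(i, j, beta, params = model_params()) {
  if (isTRUE(i$is_resource))
    stop("resources do not feed: consumer must not be a resource", call. = FALSE)
  ps <- trait_pair_sum(i$traits, j$traits, beta)
  max(0, ps) * params$b1 *
    exp(-(log(i$bodysize) - log(j$bodysize) - 3)^2 / params$b2)
}

#' Competition coefficient between two consumers of a shared prey
#'
#' \deqn{\alpha_{i,k} = a_1 \left(a_2 + (1 - a_2) \frac{q_{i,k}}{10}
#'   \exp(-(\ln s_i - \ln s_k)^2 / a_3)\right)}
#'
#' where \eqn{q_{i,k}} is the number of shared traits. Intraspecific
#' competition is strongest (\eqn{\alpha_{i,i} = a_1 = 0.866}) and the
#' coefficient decays towards the floor \eqn{a_1 a_2 = 0.6} as species
#' share fewer traits or differ more in log-bodysize.
#'
#' @inheritParams shared_traits
#' @param params \code{\link{model_params}}.
#' @return Coefficient in \eqn{[a_1 a_2, a_1]}; symmetric.
#' @export
competition_coefficient <- function(i, k, params = model_params()) {
  q <- shared_traits(i, k)
  competition_kernel(q, log(i$bodysize) - log(k$bodysize), params)
}

# vectorized alpha kernel on (q, dlns)
competition_kernel <- function(q, dlns, params) {
  params$a1 * (params$a2 + (1 - params$a2) *
                 (q / params$traits_per_species) * exp(-dlns^2 / params$a3))
}

# vectorized feeding kernel on (clipped pair sum, dlns = ln s_i - ln s_j)
feeding_kernel <- function(pair_sum, dlns, params) {
  pmax(0, pair_sum) * params$b1 * exp(-(dlns - 3)^2 / params$b2)
}

#' Draw a random trait set
#'
#' @param params \code{\link{model_params}}.
#' @return Integer vector of \code{params$traits_per_species} distinct trait
#'   labels drawn without replacement from the pool.
#' @export
random_traits <- function(params = model_params()) {
  sample.int(params$trait_pool_size, params$traits_per_species)
}
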