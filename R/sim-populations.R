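#' Specification for a two-species microsatellite population simulation
#'
#' Describes a haploid two-species sampling design evolving under a strict
#' (single-step) stepwise mutation model with reflecting allele-range
#' bounds. Defaults emulate the study design behind the popgen arm: 39
#' trinucleotide loci in four positional categories (11 OUT, 9 UP, 13 IN,
#' 6 DOWN), an invasive species sampled from 2 populations (20 genotypes)
#' that passed a founder bottleneck, and a native species sampled from 3
#' populations (31 genotypes), 51 genotypes in all. Loci inside or near
#' genes (IN, UP) carry narrower allele-range bounds than loci away from
#' transcribed sequence, modelling size constraint as a reflecting range
#' rather than an explicit selection coefficient.
#'
#' @param loci_per_category Named integer vector: loci per OUT/UP/IN/DOWN.
#' @param ancestral_repeats Named integer vector: ancestral repeat count
#'   per category.
#' @param mu Named numeric vector: mutation rate (steps per generation) per
#'   category.
#' @param bounds Named list of length-2 integer vectors `c(r_min, r_max)`
#'   per category; alleles reflect at the bounds.
#' @param t_species,t_pops Species and population split times
#'   (generations ago); `t_species > t_pops`. Population-founder lineages
#'   run from `t_pops` to `t_pops/2`, and individual lineages (a star
#'   within each population) from `t_pops/2` to the present.
#' @param pops_per_species Integer vector: populations per species
#'   (species 1 is the invasive, bottlenecked one).
#' @param inds_per_pop List of integer vectors: individuals per population,
#'   per species.
#' @param founders Founder count for the invasive species' introduction:
#'   all its individuals descend from this many lineages.
#' @param unit_length Motif length in bp (allele size = repeats x
#'   unit_length + flank_bp).
#' @param flank_bp Constant flanking length added to every allele size.
#' @param seed Integer seed.
#' @return List of class `pop_sim_spec`.
#' @export
pop_sim_spec <- function(loci_per_category = c(OUT = 11L, UP = 9L,
                                               IN = 13L, DOWN = 6L),
                         ancestral_repeats = c(OUT = 20L, UP = 15L,
                                               IN = 9L, DOWN = 18L),
                         mu = c(OUT = 0.002, UP = 0.002, IN = 0.002,
                                DOWN = 0.002),
                         bounds = list(OUT = c(5L, 60L), UP = c(8L, 30L),
                                       IN = c(6L, 13L), DOWN = c(5L, 50L)),
                         t_species = 2000L, t_pops = 400L,
                         pops_per_species = c(2L, 3L),
                         inds_per_pop = list(c(10L, 10L), c(10L, 10L, 11L)),
                         founders = 2L,
                         unit_length = 3L, flank_bp = 90L, seed = 1L) {
  cats <- names(loci_per_category)
  if (is.null(cats) || !setequal(cats, c("OUT", "UP", "IN", "DOWN")))
    stop("loci_per_category must be named OUT, UP, IN, DOWN")
  if (any(mu < 0)) stop("mutation rates must be non-negative")
  if (t_species < 0 || t_pops < 0) stop("split times must be non-negative")
  if (t_pops > t_species) stop("t_pops must not exceed t_species")
  for (cat in cats) {
    b <- bounds[[cat]]
    if (ancestral_repeats[[cat]] < b[1] || ancestral_repeats[[cat]] > b[2])
      stop("ancestral repeat count outside bounds for category ", cat)
  }
  if (length(pops_per_species) != length(inds_per_pop) ||
      any(pops_per_species != lengths(inds_per_pop)))
    stop("inds_per_pop must give one count per population per species")
  if (founders < 1L) stop("founders must be >= 1")
  structure(list(loci_per_category = loci_per_category,
                 ancestral_repeats = ancestral_repeats, mu = mu,
                 bounds = bounds, t_species = t_species, t_pops = t_pops,
                 pops_per_species = pops_per_species,
                 inds_per_pop = inds_per_pop, founders = founders,
                 unit_length = unit_length, flank_bp = flank_bp,
                 seed = seed),
            class = "pop_sim_spec")
}

# one SMM branch: Poisson(mu * t) +/-1 steps, reflecting at [r_min, r_max]
.smm_branch <- function(repeats, t, mu, r_min, r_max) {
  n_steps <- rpois(length(repeats), mu * t)
  for (i in seq_along(repeats)) {
    r <- repeats[i]
    if (n_steps[i] > 0) {
      for (s in seq_len(n_steps[i])) {
        step <- if (runif(1) < 0.5) -1L else 1L
        r2 <- r + step
        if (r2 < r_min || r2 > r_max) r2 <- r - step  # reflect
        r <- max(r_min, min(r_max, r2))
      }
    }
    repeats[i] <- r
  }
  repeats
}

#' Simulate two-species microsatellite populations
#'
#' Evolves haploid multilocus genotypes down a fixed lineage tree under the
#' bounded strict stepwise mutation model: an ancestral genotype splits into
#' one lineage per species at `t_species`; each species lineage runs to
#' `t_pops`, where population-founder lineages branch and run to
#' `t_pops/2`; individuals then form a star within each population,
#' evolving independently to the present. For the invasive species
#' (species 1) the population founders are drawn, with replacement, from
#' `founders` bottleneck lineages. Allele sizes are emitted as
#' `repeats * unit_length + flank_bp`.
#'
#' @param spec A `pop_sim_spec`.
#' @return List with `genotypes` (a [genotype_matrix()]), `truth`
#'   (ancestral repeats, per-lineage founder states, and the spec).
#' @export
simulate_populations <- function(spec) {
  stopifnot(inherits(spec, "pop_sim_spec"))
  .restore_seed(.simulate_pops_impl(spec), spec$seed)
}

.simulate_pops_impl <- function(spec) {
  cats <- rep(names(spec$loci_per_category), spec$loci_per_category)
  n_loci <- length(cats)
  loci_ids <- sprintf("MS%02d", seq_len(n_loci))
  mu <- spec$mu[cats]
  r_min <- vapply(spec$bounds[cats], `[`, integer(1), 1L)
  r_max <- vapply(spec$bounds[cats], `[`, integer(1), 2L)
  anc <- spec$ancestral_repeats[cats]

  branch <- function(state, t) {
    out <- state
    for (l in seq_len(n_loci))
      out[l] <- .smm_branch(state[l], t, mu[l], r_min[l], r_max[l])
    out
  }

  t_mid <- spec$t_pops / 2
  n_species <- length(spec$pops_per_species)
  species_ids <- paste0("species", seq_len(n_species))
  rows <- list(); pop_lab <- character(); sp_lab <- character()
  founder_of <- character()
  species_states <- list()
  for (s in seq_len(n_species)) {
    sp_state <- branch(anc, spec$t_species - spec$t_pops)
    species_states[[s]] <- sp_state
    # bottleneck pool for the invasive species; one lineage per population
    # founder otherwise
    if (s == 1L && spec$founders > 0L) {
      pool <- lapply(seq_len(spec$founders), function(f)
        branch(sp_state, spec$t_pops - t_mid))
      pop_states <- lapply(seq_len(spec$pops_per_species[s]), function(p) {
        pick <- sample.int(spec$founders, 1L)
        list(state = pool[[pick]], founder = paste0("F", pick))
      })
    } else {
      pop_states <- lapply(seq_len(spec$pops_per_species[s]), function(p)
        list(state = branch(sp_state, spec$t_pops - t_mid),
             founder = paste0("P", p)))
    }
    for (p in seq_len(spec$pops_per_species[s])) {
      pname <- sprintf("%s_pop%d", species_ids[s], p)
      for (i in seq_len(spec$inds_per_pop[[s]][p])) {
        geno <- branch(pop_states[[p]]$state, t_mid)
        rows[[length(rows) + 1L]] <- geno
        pop_lab <- c(pop_lab, pname)
        sp_lab <- c(sp_lab, species_ids[s])
        founder_of <- c(founder_of,
                        paste0(species_ids[s], ".", pop_states[[p]]$founder))
      }
    }
  }
  repeats <- do.call(rbind, rows)
  sizes <- repeats * spec$unit_length + spec$flank_bp
  rownames(sizes) <- sprintf("%s_i%02d", pop_lab,
                             stats::ave(seq_along(pop_lab), pop_lab,
                                        FUN = seq_along))
  colnames(sizes) <- loci_ids
  g <- genotype_matrix(sizes, pop_lab, sp_lab, locus_category = cats)
  list(genotypes = g,
       truth = list(ancestral_repeats = setNames(anc, loci_ids),
                    repeats = repeats, founder = founder_of,
                    species_states = species_states, spec = spec))
}
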