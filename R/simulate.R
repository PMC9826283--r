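# Forward simulator for clinal contact zones: founders along a transect,
# generations of spatially local mating with Haldane/Poisson recombination of
# background SNPs, inversion karyotypes drawn from logistic clines, and a
# trait with known variance shares.

#' Configure a contact-zone simulation
#'
#' The transect runs from the Wave habitat (position 0) into the Crab
#' habitat, mirroring the sampling design of rocky-shore snail contact
#' zones. Inversion arrangement frequencies follow logistic clines; the
#' trait is a sum of components (sex, habitat plasticity, shore height, one
#' per inversion, polygenic breeding value, residual) each scaled so its
#' sample variance equals its target share of a unit total.
#'
#' @param site site label.
#' @param n number of sampled individuals.
#' @param length_m transect path length in metres.
#' @param n_generations generations of local mating after the founders
#'   (0 = sample the founders directly).
#' @param dispersal_sd_m SD (metres) of the Gaussian used both for mate
#'   choice and offspring displacement.
#' @param n_neutral_snps background SNPs outside inversions.
#' @param n_lgs number of linkage groups.
#' @param lg_length_cm map length of each linkage group (centimorgans).
#' @param inversions data frame: `name`, `lg`, `cm_start`, `cm_end`,
#'   `center_m`, `width_m` (cline center/width), `p_wave`, `p_crab`
#'   (arrangement frequency at the Wave/Crab transect ends), `divergence`
#'   (absolute allele-frequency difference between arrangements at region
#'   SNPs), `n_snps` (SNPs in the region), `share` (target variance share of
#'   the inversion's additive effect). `NULL` gives two generic inversions.
#' @param h2 target narrow-sense heritability (polygenic share).
#' @param sex_share,habitat_share,shore_share target variance shares of the
#'   sex, habitat-plasticity and shore-height components.
#' @param env_width_m width of the logistic habitat transition.
#' @param transition_halfwidth_m half-width (metres) of the zone labelled
#'   `transition` around the habitat boundary.
#' @param env_n_points number of environmental survey points.
#' @param env_noise indicator noise rate at the survey points.
#' @param secondary_contact if `TRUE`, individuals landing in the transition
#'   zone in the final generation are independent crosses of one Wave-flank
#'   and one Crab-flank parent (migrant/hybrid scenario) instead of locally
#'   bred.
#' @param seed RNG seed; the simulation is a deterministic function of the
#'   config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(site = "SIM", n = 400, length_m = 300,
                       n_generations = 3, dispersal_sd_m = 5,
                       n_neutral_snps = 2000, n_lgs = 17,
                       lg_length_cm = 50, inversions = NULL,
                       h2 = 0.3, sex_share = 0.02, habitat_share = 0.05,
                       shore_share = 0.02, env_width_m = 20,
                       transition_halfwidth_m = 30, env_n_points = 1500,
                       env_noise = 0.1, secondary_contact = FALSE,
                       seed = 1) {
  if (is.null(inversions))
    inversions <- data.frame(
      name = c("LGC6.1", "LGC12.2"), lg = c(6L, 12L),
      cm_start = c(10, 15), cm_end = c(25, 32),
      center_m = length_m / 2, width_m = 20,
      p_wave = 0.85, p_crab = 0.15, divergence = 0.6,
      n_snps = 30L, share = c(0.06, 0.04),
      stringsAsFactors = FALSE)
  stopifnot(all(c("name", "lg", "cm_start", "cm_end", "center_m", "width_m",
                  "p_wave", "p_crab", "divergence", "n_snps", "share") %in%
                  names(inversions)))
  if (any(inversions$p_wave < 0 | inversions$p_wave > 1 |
            inversions$p_crab < 0 | inversions$p_crab > 1))
    stop("arrangement frequencies must lie in [0, 1]")
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  total_share <- h2 + sex_share + habitat_share + shore_share +
    sum(inversions$share)
  if (total_share >= 1)
    stop("infeasible variance shares: components sum to ",
         round(total_share, 3), " >= 1")
  structure(list(site = site, n = n, length_m = length_m,
                 n_generations = n_generations,
                 dispersal_sd_m = dispersal_sd_m,
                 n_neutral_snps = n_neutral_snps, n_lgs = n_lgs,
                 lg_length_cm = lg_length_cm, inversions = inversions,
                 h2 = h2, sex_share = sex_share,
                 habitat_share = habitat_share, shore_share = shore_share,
                 env_width_m = env_width_m,
                 transition_halfwidth_m = transition_halfwidth_m,
                 env_n_points = env_n_points, env_noise = env_noise,
                 secondary_contact = secondary_contact, seed = seed),
            class = "sim_config")
}

#' Configuration mimicking the three-island study design
#'
#' Three sites with the published sample sizes and path lengths (CZA: 379
#' snails / 362.47 m, CZB: 381 / 257.00 m, CZD: 370 / 270.17 m), 16
#' polymorphic inversions spread over a 17-linkage-group map, clinal
#' arrangement frequencies, and a polygenic trait with sexual dimorphism and
#' habitat plasticity.
#'
#' @param n_neutral_snps background SNP count per site (desk scale).
#' @param seed base RNG seed; site s uses `seed + s`.
#' @return list with `sites` (data frame) and `configs` (named list of
#'   [sim_config()] objects, one per site).
#' @export
default_paper_like_config <- function(n_neutral_snps = 2000, seed = 1) {
  sites <- data.frame(site = c("CZA", "CZB", "CZD"),
                      n = c(379L, 381L, 370L),
                      length_m = c(362.47, 257.00, 270.17),
                      stringsAsFactors = FALSE)
  inv_lg <- c(1, 1, 2, 4, 6, 6, 7, 9, 10, 10, 11, 12, 12, 12, 12, 14)
  inv_name <- unlist(lapply(split(inv_lg, inv_lg), function(v)
    paste0("LGC", v[1], ".", seq_along(v))), use.names = FALSE)
  nv <- length(inv_lg)
  share <- rep(0.008, nv)
  share[inv_name %in% c("LGC6.1", "LGC12.2")] <- 0.03
  configs <- list()
  for (s in seq_len(nrow(sites))) {
    L <- sites$length_m[s]
    inversions <- data.frame(
      name = inv_name, lg = as.integer(inv_lg),
      cm_start = 10 + 2 * seq_len(nv) %% 5,
      cm_end = 28 + 2 * seq_len(nv) %% 5,
      center_m = L / 2, width_m = 20,
      p_wave = 0.8, p_crab = 0.2, divergence = 0.5,
      n_snps = 20L, share = share, stringsAsFactors = FALSE)
    configs[[sites$site[s]]] <- sim_config(
      site = sites$site[s], n = sites$n[s], length_m = L,
      n_neutral_snps = n_neutral_snps, n_lgs = 17,
      inversions = inversions, h2 = 0.3, sex_share = 0.03,
      habitat_share = 0.05, shore_share = 0.02, seed = seed + s)
  }
  list(sites = sites, configs = configs)
}

#' Logistic cline in arrangement frequency along the transect
#'
#' Frequency of the counted arrangement at path position `x`:
#' `p_wave` at the Wave end (position 0), `p_crab` at the Crab end, with a
#' logistic transition of width `width_m` centred at `center_m`; the
#' frequency at the centre is the midpoint `(p_wave + p_crab) / 2`.
#'
#' @param x path positions (metres).
#' @param center_m,width_m cline centre and width.
#' @param p_wave,p_crab end frequencies.
#' @return frequencies in `[0, 1]`.
#' @export
cline_frequency <- function(x, center_m, width_m, p_wave, p_crab) {
  p_wave + (p_crab - p_wave) * plogis((x - center_m) / width_m)
}

# One gamete: recombine two parental haplotypes over the map.
# Crossover count per LG is Poisson in its map length (Haldane, no
# interference); crossover positions uniform in cM.
make_gamete <- function(h1, h2, lg_snp_idx, lg_cm, lg_len) {
  out <- h1
  for (l in seq_along(lg_snp_idx)) {
    idx <- lg_snp_idx[[l]]
    start <- sample.int(2L, 1L)
    k <- rpois(1, lg_len / 100)
    if (k == 0) {
      if (start == 2L) out[idx] <- h2[idx]
    } else {
      bp <- sort(runif(k, 0, lg_len))
      seg <- findInterval(lg_cm[[l]], bp)
      hap <- ((start - 1L + seg) %% 2L) + 1L
      two <- idx[hap == 2L]
      out[two] <- h2[two]
    }
  }
  out
}

#' Simulate a contact-zone dataset with ground truth
#'
#' Runs the forward model described in [sim_config()]: founders with
#' independent background genotypes are placed along the transect, then
#' `n_generations` of spatially local mating (mates drawn with Gaussian
#' weight in distance, offspring displaced by the same SD) with
#' recombination of the background SNPs over the linkage map. Inversion
#' karyotypes and their region SNPs are imposed at the sampled generation
#' from the local cline frequency (soft-selection shortcut), with
#' arrangement-specific allele frequencies differing by the configured
#' divergence and no recombination between arrangements within a region.
#' The trait is assembled from components scaled to their target variance
#' shares; all generative components are stored as ground truth.
#'
#' @param cfg a [sim_config()].
#' @return list of class `contact_zone_sim`:
#'   `genotypes` (a [genotype_matrix()] with map annotation: background plus
#'   region SNPs), `samples` (sample table with `trait` column), `env_points`
#'   (survey points), `regions` (an [inversion_regions()] table), and `truth`
#'   (karyotypes, per-sample components, target and realized variance shares,
#'   pedigree of the final generation).
#' @export
simulate_contact_zone <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  L <- cfg$length_m
  c0 <- L / 2
  tw <- cfg$transition_halfwidth_m
  disp <- cfg$dispersal_sd_m
  m <- cfg$n_neutral_snps

  # background map, sorted within linkage group
  lg <- rep_len(seq_len(cfg$n_lgs), m)
  cm <- runif(m, 0, cfg$lg_length_cm)
  ord <- order(lg, cm)
  lg <- lg[ord]; cm <- cm[ord]
  lg_snp_idx <- split(seq_len(m), lg)
  lg_cm <- split(cm, lg)

  # founders: independent genotypes, uniform positions
  f <- runif(m, 0.1, 0.9)
  H1 <- matrix(rbinom(n * m, 1, rep(f, each = n)), n, m)
  H2 <- matrix(rbinom(n * m, 1, rep(f, each = n)), n, m)
  x <- runif(n, 0, L)
  mo <- fa <- rep(NA_integer_, n)

  if (cfg$n_generations > 0) {
    for (g in seq_len(cfg$n_generations)) {
      final <- g == cfg$n_generations
      mo <- sample.int(n, n, replace = TRUE)
      fa <- integer(n)
      for (i in seq_len(n)) {
        wgt <- dnorm(x - x[mo[i]], sd = disp)
        wgt[mo[i]] <- 0
        fa[i] <- sample.int(n, 1, prob = wgt)
      }
      childx <- pmin(pmax(x[mo] + rnorm(n, 0, disp), 0), L)
      if (cfg$secondary_contact && final) {
        tz <- childx >= c0 - tw & childx <= c0 + tw
        left <- which(x < c0 - tw)
        right <- which(x > c0 + tw)
        if (length(left) && length(right) && any(tz)) {
          mo[tz] <- sample(left, sum(tz), replace = TRUE)
          fa[tz] <- sample(right, sum(tz), replace = TRUE)
        }
      }
      N1 <- matrix(0L, n, m)
      N2 <- matrix(0L, n, m)
      for (i in seq_len(n)) {
        N1[i, ] <- make_gamete(H1[mo[i], ], H2[mo[i], ], lg_snp_idx, lg_cm,
                               cfg$lg_length_cm)
        N2[i, ] <- make_gamete(H1[fa[i], ], H2[fa[i], ], lg_snp_idx, lg_cm,
                               cfg$lg_length_cm)
      }
      H1 <- N1; H2 <- N2; x <- childx
    }
  }
  D_bg <- H1 + H2

  # inversion karyotypes from logistic clines; region SNPs conditional on
  # arrangement
  inv <- cfg$inversions
  nv <- nrow(inv)
  K <- matrix(NA_integer_, n, nv, dimnames = list(NULL, inv$name))
  reg_dos <- NULL
  reg_meta <- NULL
  for (v in seq_len(nv)) {
    pv <- cline_frequency(x, inv$center_m[v], inv$width_m[v],
                          inv$p_wave[v], inv$p_crab[v])
    K[, v] <- rbinom(n, 2, pv)
    ns <- inv$n_snps[v]
    d <- inv$divergence[v]
    q0 <- runif(ns, 0.05, 0.95 - d)
    q1 <- q0 + d
    dos <- matrix(0L, n, ns)
    for (j in seq_len(ns))
      dos[, j] <- rbinom(n, K[, v], q1[j]) + rbinom(n, 2L - K[, v], q0[j])
    cmr <- sort(runif(ns, inv$cm_start[v], inv$cm_end[v]))
    reg_dos <- cbind(reg_dos, dos)
    reg_meta <- rbind(reg_meta, data.frame(
      id = sprintf("%s_snp%03d", inv$name[v], seq_len(ns)),
      lg = inv$lg[v], cm = cmr, stringsAsFactors = FALSE))
  }

  dosage <- cbind(D_bg, reg_dos)
  snps <- data.frame(
    id = c(sprintf("bg%05d", seq_len(m)), reg_meta$id),
    chrom = as.character(c(lg, reg_meta$lg)),
    pos = seq_len(m + nrow(reg_meta)),
    qual = runif(m + nrow(reg_meta), 30, 60),
    ref = "A", alt = "T", biallelic = TRUE,
    lg = as.integer(c(lg, reg_meta$lg)),
    cm = c(cm, reg_meta$cm),
    stringsAsFactors = FALSE)
  ids <- sprintf("%s_%04d", cfg$site, seq_len(n))
  geno <- genotype_matrix(dosage, ids, snps)

  # sample covariates and trait components
  sex <- sample(c("F", "M"), n, replace = TRUE)
  shore <- rnorm(n, 1.5, 0.5)
  wave_score <- 1 - plogis((x - c0) / cfg$env_width_m)
  zc <- function(v, nm) {
    s <- sd(v)
    if (s == 0) stop("degenerate simulated component '", nm,
                     "': zero variance")
    (v - mean(v)) / s
  }
  poly <- apply(D_bg, 2, sd) > 0
  b <- rnorm(sum(poly))
  bv_raw <- scale(D_bg[, poly, drop = FALSE]) %*% b
  shares <- c(sex = cfg$sex_share, habitat = cfg$habitat_share,
              shore = cfg$shore_share,
              setNames(inv$share, inv$name), V_A = cfg$h2)
  comps <- list(
    sex = zc(as.numeric(sex == "M"), "sex") * sqrt(cfg$sex_share),
    habitat = zc(wave_score, "habitat") * sqrt(cfg$habitat_share),
    shore = zc(shore, "shore") * sqrt(cfg$shore_share))
  for (v in seq_len(nv))
    comps[[inv$name[v]]] <- zc(K[, v], inv$name[v]) * sqrt(inv$share[v])
  comps <- do.call(cbind, comps)
  bv <- zc(drop(bv_raw), "breeding value") * sqrt(cfg$h2)
  resid_share <- 1 - sum(shares)
  e <- zc(rnorm(n), "residual") * sqrt(resid_share)
  y <- rowSums(comps) + bv + e

  habitat_label <- ifelse(x < c0 - tw, "Wave",
                          ifelse(x > c0 + tw, "Crab", "transition"))
  samples <- data.frame(
    id = ids, site = cfg$site, path_pos_m = x, shore_height_m = shore,
    sex = sex, habitat_label = habitat_label,
    dist_center_m = abs(x - (c0 + L) / 2),
    trait = y, stringsAsFactors = FALSE)

  # environmental survey points: noisy step functions of habitat
  np <- cfg$env_n_points
  ex <- sort(runif(np, 0, L))
  crab_pe <- plogis((ex - c0) / cfg$env_width_m)
  noise <- cfg$env_noise
  p_wave_side <- (1 - noise) * (1 - crab_pe) + noise / 2
  env_points <- data.frame(
    path_pos_m = ex,
    substrate = rbinom(np, 1, p_wave_side),
    barnacles = rbinom(np, 1, p_wave_side),
    fucus = rbinom(np, 1, (1 - noise) * crab_pe + noise / 2))

  vy <- var(y)
  all_comps <- cbind(comps, V_A = bv, residual = e)
  truth <- list(
    karyotypes = K,
    components = as.data.frame(all_comps),
    breeding_value = bv,
    shares_target = c(shares, residual = resid_share),
    shares_realized = apply(all_comps, 2, var) / vy,
    var_y = vy,
    pedigree = if (cfg$n_generations > 0)
      data.frame(mother = mo, father = fa) else NULL,
    config = cfg)

  structure(list(genotypes = geno, samples = samples,
                 env_points = env_points,
                 regions = inversion_regions(inv$name, inv$lg,
                                             inv$cm_start, inv$cm_end),
                 truth = truth),
            class = "contact_zone_sim")
}

#' @export
print.contact_zone_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("contact_zone_sim: site %s, n = %d, %.0f m transect\n",
              cfg$site, cfg$n, cfg$length_m))
  cat(sprintf("  %d background SNPs, %d inversions, %d generations\n",
              cfg$n_neutral_snps, nrow(cfg$inversions),
              cfg$n_generations))
  cat("  realized shares: ",
      paste(sprintf("%s=%.3f", names(x$truth$shares_realized),
                    x$truth$shares_realized), collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the VCF, sample TSV, environment TSV and (optionally) a truth JSON
#' for a simulated contact zone.
#'
#' @param sim a [simulate_contact_zone()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "contact_zone_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f_vcf <- file.path(dir, "genotypes.vcf")
  f_smp <- file.path(dir, "samples.tsv")
  f_env <- file.path(dir, "env_points.tsv")
  f_map <- file.path(dir, "linkage_map.tsv")
  f_reg <- file.path(dir, "inversion_regions.tsv")
  write_vcf(sim$genotypes, f_vcf)
  write.table(sim$samples, f_smp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$env_points, f_env, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(snp_id = sim$genotypes$snps$id,
                         lg = sim$genotypes$snps$lg,
                         cm = sim$genotypes$snps$cm),
              f_map, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(sim$regions), f_reg, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(vcf = f_vcf, samples = f_smp, env = f_env, map = f_map,
              regions = f_reg))
}
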