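# Ground-truthed synthetic study generator. Emulates the structure the
# analysis assumes: a diverse true community per biological sample, a
# distinct reagent-contaminant community shared by every sample and
# dominating the negative controls, partial taxon overlap between the two,
# order-of-magnitude differences in total bacterial load between groups,
# and the study design (21 calves sampled at birth / 24 h / 7 d, 10 dams at
# three body sites, 3 empty-swab controls). Observed reads mix the true and
# contaminant communities in proportion to their 16S copy numbers.

#' Synthetic study configuration
#'
#' Defaults encode the emulated study's conditions: 21 calves at three time
#' points, 10 dams at three body sites, 3 negative controls; reagent
#' background of 1.3e5 16S copies per swab; newborn load 5.7e5 copies per
#' swab, 24 h load about 7000-fold the newborn load and 7 d about 14-fold
#' the 24 h load; sequencing depths set to per-group raw-read medians of
#' the emulated dataset. Adult body-site loads (not reported per swab in
#' the emulated study) are set to realistic high-biomass values so that
#' reagent contamination is negligible there.
#'
#' @param seed integer RNG seed; the whole study is deterministic given it.
#' @param n_calves,n_dams,n_controls design sizes.
#' @param taxon_pool_size number of true-community genotypes.
#' @param contaminant_pool_size number of contaminant-community genotypes.
#' @param shared_pool_fraction fraction (of the smaller pool) of genotypes
#'   present in both communities.
#' @param contamination_copies reagent 16S copies per sample.
#' @param load_by_group named vector of true 16S copies per swab per group.
#' @param depth_by_group named vector of sequencing reads per sample.
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of
#'   community profile weights.
#' @param source_mixture mixing weights of the dam body-site communities in
#'   a newborn's community (planted vertical-transmission truth); must sum
#'   to 1. The default is oral-weighted.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_calves = 21L, n_dams = 10L, n_controls = 3L,
                             taxon_pool_size = 160L,
                             contaminant_pool_size = 40L,
                             shared_pool_fraction = 0.1,
                             contamination_copies = 1.3e5,
                             load_by_group = c(newborn = 5.7e5,
                                               calf_24h = 7000 * 5.7e5,
                                               calf_7d = 14 * 7000 * 5.7e5,
                                               dam_feces = 1e9,
                                               dam_oral = 2e8,
                                               dam_vestibule = 2e8),
                             depth_by_group = c(newborn = 21342,
                                                calf_24h = 76993,
                                                calf_7d = 47755,
                                                dam_feces = 25579,
                                                dam_oral = 51539,
                                                dam_vestibule = 39464,
                                                control = 4486),
                             abundance_meanlog = 0,
                             abundance_sdlog = 1.5,
                             source_mixture = c(dam_oral = 0.75,
                                                dam_vestibule = 0.15,
                                                dam_feces = 0.10)) {
  stopifnot(n_calves >= 1, n_dams >= 1, n_dams <= n_calves, n_controls >= 1,
            taxon_pool_size >= 1, contaminant_pool_size >= 1,
            shared_pool_fraction >= 0, shared_pool_fraction <= 1,
            contamination_copies > 0,
            all(load_by_group > 0), all(depth_by_group >= 1),
            abundance_sdlog > 0,
            abs(sum(source_mixture) - 1) < 1e-9, all(source_mixture >= 0))
  structure(list(seed = as.integer(seed), n_calves = as.integer(n_calves),
                 n_dams = as.integer(n_dams),
                 n_controls = as.integer(n_controls),
                 taxon_pool_size = as.integer(taxon_pool_size),
                 contaminant_pool_size = as.integer(contaminant_pool_size),
                 shared_pool_fraction = shared_pool_fraction,
                 contamination_copies = contamination_copies,
                 load_by_group = load_by_group,
                 depth_by_group = depth_by_group,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 source_mixture = source_mixture),
            class = "synthetic_config")
}

# Genus bank with RDP-style lineages and a coarse ecological role used to
# bias site/age profiles. Roles: oral, fecal, vaginal, skin (environmental
# newborn flora), early (facultative first-day colonisers), contaminant
# (typical reagent flora).
.genus_bank <- function() {
  g <- function(phylum, class, order, family, genus, role)
    data.frame(domain = "Bacteria", phylum = phylum, class = class,
               order = order, family = family, genus = genus, role = role,
               stringsAsFactors = FALSE)
  rbind(
    g("Firmicutes", "Bacilli", "Bacillales", "Staphylococcaceae", "Staphylococcus", "skin"),
    g("Firmicutes", "Bacilli", "Lactobacillales", "Streptococcaceae", "Streptococcus", "oral"),
    g("Firmicutes", "Bacilli", "Lactobacillales", "Lactobacillaceae", "Lactobacillus", "vaginal"),
    g("Firmicutes", "Bacilli", "Lactobacillales", "Enterococcaceae", "Enterococcus", "early"),
    g("Firmicutes", "Clostridia", "Clostridiales", "Clostridiaceae-1", "Clostridium-sensu-stricto", "early"),
    g("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "Clostridium-XlVa", "fecal"),
    g("Firmicutes", "Clostridia", "Clostridiales", "Peptostreptococcaceae", "Romboutsia", "fecal"),
    g("Firmicutes", "Clostridia", "Clostridiales", "Peptostreptococcaceae", "Terrisporobacter", "early"),
    g("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae", "Faecalibacterium", "fecal"),
    g("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae", "Butyricicoccus", "fecal"),
    g("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae", "Ruminococcus", "fecal"),
    g("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "Blautia", "fecal"),
    g("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "unclassified_Lachnospiraceae", "fecal"),
    g("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae", "unclassified_Ruminococcaceae", "fecal"),
    g("Proteobacteria", "Gammaproteobacteria", "Enterobacteriales", "Enterobacteriaceae", "Escherichia/Shigella", "early"),
    g("Proteobacteria", "Gammaproteobacteria", "Enterobacteriales", "Enterobacteriaceae", "unclassified_Enterobacteriaceae", "skin"),
    g("Proteobacteria", "Gammaproteobacteria", "Pseudomonadales", "Moraxellaceae", "Acinetobacter", "skin"),
    g("Proteobacteria", "Gammaproteobacteria", "Pseudomonadales", "Moraxellaceae", "Moraxella", "oral"),
    g("Proteobacteria", "Gammaproteobacteria", "Pseudomonadales", "Moraxellaceae", "Psychrobacter", "skin"),
    g("Proteobacteria", "Gammaproteobacteria", "Pasteurellales", "Pasteurellaceae", "unclassified_Pasteurellaceae", "oral"),
    g("Proteobacteria", "Betaproteobacteria", "Neisseriales", "Neisseriaceae", "Neisseria", "oral"),
    g("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Comamonadaceae", "Comamonas", "skin"),
    g("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Oxalobacteraceae", "Massilia", "skin"),
    g("Proteobacteria", "Alphaproteobacteria", "Rhodobacterales", "Rhodobacteraceae", "Paracoccus", "skin"),
    g("Proteobacteria", "Alphaproteobacteria", "Caulobacterales", "Caulobacteraceae", "Brevundimonas", "skin"),
    g("Actinobacteria", "Actinobacteria", "Actinomycetales", "Corynebacteriaceae", "Corynebacterium", "vaginal"),
    g("Actinobacteria", "Actinobacteria", "Actinomycetales", "Dermabacteraceae", "Brachybacterium", "skin"),
    g("Actinobacteria", "Actinobacteria", "Actinomycetales", "Micrococcaceae", "Kocuria", "skin"),
    g("Actinobacteria", "Actinobacteria", "Actinomycetales", "Micrococcaceae", "Micrococcus", "skin"),
    g("Actinobacteria", "Actinobacteria", "Actinomycetales", "Micrococcaceae", "Rothia", "oral"),
    g("Actinobacteria", "Actinobacteria", "Actinomycetales", "Actinomycetaceae", "Actinomyces", "oral"),
    g("Actinobacteria", "Actinobacteria", "Bifidobacteriales", "Bifidobacteriaceae", "Bifidobacterium", "fecal"),
    g("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Bacteroidaceae", "Bacteroides", "fecal"),
    g("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Prevotellaceae", "Prevotella", "oral"),
    g("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Prevotellaceae", "Alloprevotella", "oral"),
    g("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Porphyromonadaceae", "Porphyromonas", "vaginal"),
    g("Bacteroidetes", "unclassified_Bacteroidetes", "unclassified_Bacteroidetes", "unclassified_Bacteroidetes", "unclassified_Bacteroidetes", "vaginal"),
    # typical reagent/instrument flora
    g("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Burkholderiaceae", "Ralstonia", "contaminant"),
    g("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Burkholderiaceae", "Burkholderia", "contaminant"),
    g("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Burkholderiaceae", "Cupriavidus", "contaminant"),
    g("Proteobacteria", "Gammaproteobacteria", "Pseudomonadales", "Pseudomonadaceae", "Pseudomonas", "contaminant"),
    g("Proteobacteria", "Alphaproteobacteria", "Sphingomonadales", "Sphingomonadaceae", "Sphingomonas", "contaminant"),
    g("Proteobacteria", "Alphaproteobacteria", "Rhizobiales", "Methylobacteriaceae", "Methylobacterium", "contaminant"),
    g("Proteobacteria", "Alphaproteobacteria", "Rhizobiales", "Bradyrhizobiaceae", "Bradyrhizobium", "contaminant"),
    g("Proteobacteria", "Alphaproteobacteria", "Rhizobiales", "Phyllobacteriaceae", "Phyllobacterium", "contaminant"),
    g("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Comamonadaceae", "Delftia", "contaminant"),
    g("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Comamonadaceae", "Acidovorax", "contaminant"),
    g("Proteobacteria", "Gammaproteobacteria", "Xanthomonadales", "Xanthomonadaceae", "Stenotrophomonas", "contaminant"),
    g("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Oxalobacteraceae", "Herbaspirillum", "contaminant")
  )
}

#' Generate the true and contaminant genotype pools
#'
#' Draws `taxon_pool_size` true-community genotypes and
#' `contaminant_pool_size` contaminant genotypes over a bank of realistic
#' genera (contaminants biased toward typical reagent flora); a
#' `shared_pool_fraction` of the smaller pool belongs to both communities.
#' Deterministic under `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with `features` (data.frame `feature_id`, `genus`, `role`,
#'   `origin` in \{true_only, contaminant_only, shared\}) and `lineages`
#'   (character matrix, one row per feature).
#' @export
generate_pools <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  bank <- .genus_bank()
  true_bank <- bank[bank$role != "contaminant", , drop = FALSE]
  contam_bank <- bank[bank$role == "contaminant", , drop = FALSE]

  n_shared <- round(config$shared_pool_fraction *
                      min(config$taxon_pool_size,
                          config$contaminant_pool_size))
  if (n_shared > min(config$taxon_pool_size, config$contaminant_pool_size))
    stop("shared fraction demands more shared genotypes than the smaller pool")
  n_contam_only <- config$contaminant_pool_size - n_shared

  # every genus appears at least once when the pool is large enough
  pick <- function(b, n) {
    base <- seq_len(min(n, nrow(b)))
    extra <- if (n > nrow(b)) sample.int(nrow(b), n - nrow(b), replace = TRUE)
             else integer(0)
    b[c(base, extra), , drop = FALSE]
  }
  true_rows <- pick(true_bank, config$taxon_pool_size)
  contam_rows <- pick(contam_bank, n_contam_only)

  rows <- rbind(true_rows, contam_rows)
  origin <- c(rep("true_only", nrow(true_rows)),
              rep("contaminant_only", nrow(contam_rows)))
  shared_idx <- if (n_shared > 0)
    sample.int(nrow(true_rows), n_shared) else integer(0)
  origin[shared_idx] <- "shared"

  ids <- sprintf("gt%04d", seq_len(nrow(rows)))
  lineages <- as.matrix(rows[, TAX_RANKS])
  rownames(lineages) <- ids
  features <- data.frame(feature_id = ids, genus = rows$genus,
                         role = rows$role, origin = origin,
                         stringsAsFactors = FALSE)
  list(features = features, lineages = lineages)
}

# role -> context multiplier used to shape site/age communities
.role_multipliers <- list(
  dam_oral      = c(oral = 30, skin = 2,   vaginal = 0.5, fecal = 0.3, early = 0.5),
  dam_feces     = c(oral = 0.2, skin = 0.2, vaginal = 0.5, fecal = 30,  early = 1),
  dam_vestibule = c(oral = 0.5, skin = 3,   vaginal = 30,  fecal = 1,   early = 0.5),
  calf_7d       = c(oral = 0.2, skin = 0.2, vaginal = 2,   fecal = 10,  early = 5)
)

# genus-level target composition of the first-day (24 h) low-diversity
# facultative community; the remainder is spread thinly over other taxa
.early_targets <- c("Escherichia/Shigella" = 0.77,
                    "Clostridium-sensu-stricto" = 0.10,
                    "Enterococcus" = 0.02,
                    "Streptococcus" = 0.005,
                    "unclassified_Enterobacteriaceae" = 0.005)

# log-normal profile over the indices `idx` of an n-feature vector,
# multiplied by per-feature bias, normalised to a composition
.lnorm_profile <- function(n, idx, bias, meanlog, sdlog) {
  w <- numeric(n)
  w[idx] <- stats::rlnorm(length(idx), meanlog, sdlog) * bias[idx]
  w / sum(w)
}

#' Draw one sample's reads from the copy-number mixture model
#'
#' The observed read composition is w * true_profile +
#' (1 - w) * contaminant_profile with w = true_copies / (true_copies +
#' contaminant_copies); reads are multinomial at the given depth. Negative
#' controls use `true_copies = 0`. Uses the current RNG state.
#'
#' @param true_profile,contaminant_profile compositions over the same
#'   feature set (each sums to 1 when its copy number is positive).
#' @param true_copies,contaminant_copies 16S copy numbers of the two
#'   communities; not both zero.
#' @param depth number of reads to draw (>= 1).
#' @return integer count vector.
#' @export
generate_sample <- function(true_profile, contaminant_profile,
                            true_copies, contaminant_copies, depth) {
  stopifnot(length(true_profile) == length(contaminant_profile),
            true_copies >= 0, contaminant_copies >= 0, depth >= 1)
  if (true_copies + contaminant_copies == 0)
    stop("true and contaminant copy numbers cannot both be zero")
  w <- true_copies / (true_copies + contaminant_copies)
  if (w > 0 && abs(sum(true_profile) - 1) > 1e-6)
    stop("true_profile must be a composition")
  if (w < 1 && abs(sum(contaminant_profile) - 1) > 1e-6)
    stop("contaminant_profile must be a composition")
  mix <- w * true_profile + (1 - w) * contaminant_profile
  as.integer(stats::rmultinom(1, size = depth, prob = mix))
}

#' Generate a full ground-truthed synthetic study
#'
#' Produces the complete dataset of the emulated design: per-dam body-site
#' communities (site-specific base profiles with per-dam variation),
#' newborn communities mixed from the dam-site pools of each calf's own dam
#' according to `source_mixture` (unpaired calves draw from the population
#' site profiles), low-diversity facultative 24 h communities, anaerobe-
#' enriched 7 d communities, contaminant-only negative controls, and a
#' qPCR table whose copies are true + contaminant load with log-normal
#' measurement noise.
#'
#' @param config a [synthetic_config()].
#' @param calf_groups calf time points to generate (default all three);
#'   dams and controls are always generated.
#' @return list of class `synthetic_study` with `table`
#'   ([feature_table()]), `metadata`, `qpcr`, `truth` (list with
#'   `true_profiles`, `contaminant_profile`, `contamination_fraction`,
#'   `origin`, `true_copies`, `source_mixture`).
#' @export
generate_study <- function(config = synthetic_config(),
                           calf_groups = c("newborn", "calf_24h", "calf_7d")) {
  stopifnot(inherits(config, "synthetic_config"))
  calf_groups <- match.arg(calf_groups, several.ok = TRUE)
  pools <- generate_pools(config)  # seeds the RNG with config$seed
  feats <- pools$features
  n <- nrow(feats)
  is_true <- feats$origin %in% c("true_only", "shared")
  is_contam <- feats$origin %in% c("contaminant_only", "shared")
  role_of <- feats$role
  ml <- config$abundance_meanlog
  sl <- config$abundance_sdlog

  role_bias <- function(context) {
    m <- .role_multipliers[[context]]
    b <- rep(1, n)
    known <- role_of %in% names(m)
    b[known] <- m[role_of[known]]
    b
  }

  # single contaminant community shared by all samples and controls
  contam_profile <- .lnorm_profile(n, which(is_contam), rep(1, n), ml, sl)

  # population base profile per dam site, then per-dam variation around it
  sites <- c("dam_oral", "dam_feces", "dam_vestibule")
  base_site <- lapply(sites, function(s)
    .lnorm_profile(n, which(is_true), role_bias(s), ml, sl))
  names(base_site) <- sites
  perturb <- function(p, sd) {
    w <- p * exp(stats::rnorm(n, 0, sd))
    w / sum(w)
  }
  dam_profiles <- lapply(seq_len(config$n_dams), function(d) {
    lapply(base_site, perturb, sd = 0.8)
  })

  mix_profiles <- function(profs, weights) {
    p <- Reduce(`+`, Map(`*`, profs[names(weights)], weights))
    p / sum(p)
  }

  newborn_profile <- function(calf) {
    src <- if (calf <= config$n_dams) dam_profiles[[calf]] else base_site
    perturb(mix_profiles(src, config$source_mixture),
            if (calf <= config$n_dams) 0.3 else 0.8)
  }
  early_profile <- function() {
    w <- numeric(n)
    for (g in names(.early_targets)) {
      idx <- which(feats$genus == g & is_true)
      if (length(idx) == 0) next
      w[idx] <- .early_targets[g] / length(idx) *
        exp(stats::rnorm(length(idx), 0, 0.3))
    }
    rest <- which(is_true & w == 0)
    w[rest] <- 0.001 * stats::rlnorm(length(rest), 0, 1) / length(rest)
    w / sum(w)
  }
  week_profile <- function() {
    bias <- role_bias("calf_7d")
    boost <- feats$genus %in% c("Faecalibacterium", "Bacteroides",
                                "Lactobacillus", "Butyricicoccus")
    .lnorm_profile(n, which(is_true), bias * ifelse(boost, 20, 1), ml, 1)
  }

  samples <- list()
  add <- function(id, animal, group, dam_of, cycles, profile) {
    samples[[id]] <<- list(id = id, animal = animal, group = group,
                           dam_of = dam_of, cycles = cycles,
                           profile = profile)
  }
  for (calf in seq_len(config$n_calves)) {
    a <- sprintf("calf%02d", calf)
    if ("newborn" %in% calf_groups)
      add(paste0(a, "_newborn"), a, "newborn", NA, 21L, newborn_profile(calf))
    if ("calf_24h" %in% calf_groups)
      add(paste0(a, "_24h"), a, "calf_24h", NA, 18L, early_profile())
    if ("calf_7d" %in% calf_groups)
      add(paste0(a, "_7d"), a, "calf_7d", NA, 15L, week_profile())
  }
  for (dam in seq_len(config$n_dams)) {
    a <- sprintf("dam%02d", dam)
    calf <- sprintf("calf%02d", dam)
    add(paste0(a, "_oral"), a, "dam_oral", calf, 18L,
        dam_profiles[[dam]]$dam_oral)
    add(paste0(a, "_feces"), a, "dam_feces", calf, 15L,
        dam_profiles[[dam]]$dam_feces)
    add(paste0(a, "_vestibule"), a, "dam_vestibule", calf, 18L,
        dam_profiles[[dam]]$dam_vestibule)
  }
  for (ctl in seq_len(config$n_controls)) {
    add(sprintf("control_%d", ctl), sprintf("control_%d", ctl), "control",
        NA, 21L, numeric(n))
  }

  ids <- names(samples)
  counts <- matrix(0L, n, length(ids),
                   dimnames = list(feats$feature_id, ids))
  true_profiles <- matrix(0, n, length(ids),
                          dimnames = list(feats$feature_id, ids))
  true_copies <- contam_copies <- qpcr_copies <-
    stats::setNames(numeric(length(ids)), ids)
  for (id in ids) {
    s <- samples[[id]]
    tc <- if (s$group == "control") 0
          else config$load_by_group[s$group] * stats::rlnorm(1, 0, 0.35)
    cc <- config$contamination_copies * stats::rlnorm(1, 0, 0.25)
    depth <- max(100, round(config$depth_by_group[s$group] *
                              stats::rlnorm(1, 0, 0.25)))
    counts[, id] <- generate_sample(s$profile, contam_profile, tc, cc, depth)
    true_profiles[, id] <- s$profile
    true_copies[id] <- tc
    contam_copies[id] <- cc
    qpcr_copies[id] <- (tc + cc) * stats::rlnorm(1, 0, 0.15)
  }

  table <- feature_table(counts, pools$lineages, level = "genotype")
  metadata <- data.frame(
    sample_id = ids,
    animal_id = vapply(samples, `[[`, "", "animal"),
    group = vapply(samples, `[[`, "", "group"),
    dam_of = vapply(samples, function(s) as.character(s$dam_of), ""),
    preamp_cycles = vapply(samples, function(s) as.integer(s$cycles), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  qpcr <- data.frame(sample_id = ids,
                     group = metadata$group,
                     copies_per_swab = unname(qpcr_copies),
                     row.names = NULL, stringsAsFactors = FALSE)
  truth <- list(true_profiles = true_profiles,
                contaminant_profile = contam_profile,
                contamination_fraction = contam_copies /
                  (true_copies + contam_copies),
                origin = stats::setNames(feats$origin, feats$feature_id),
                true_copies = true_copies,
                contaminant_copies = contam_copies,
                source_mixture = config$source_mixture)
  structure(list(table = table, metadata = validate_metadata(metadata),
                 qpcr = qpcr, truth = truth, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d features x %d samples (seed %d)\n",
              nrow(x$table$counts), ncol(x$table$counts), x$config$seed))
  print(table(x$metadata$group))
  invisible(x)
}

#' Evaluate decontamination against the planted truth
#'
#' For every non-control sample, reports the fraction of contaminant-only
#' reads that were rejected (specificity proxy), the fraction of true-only
#' reads retained (sensitivity proxy), and the verdict-class split of
#' shared-origin reads.
#'
#' @param truth the `truth` element of a [generate_study()] result (or the
#'   study itself).
#' @param result the [decontaminate()] result computed on the study table.
#' @param table the original (unfiltered) study [feature_table()].
#' @return data.frame, one row per non-control sample, with read counts and
#'   fractions per origin class; fractions are NA where a sample has no
#'   reads of that origin.
#' @export
evaluate_recovery <- function(truth, result, table) {
  if (inherits(truth, "synthetic_study")) truth <- truth$truth
  stopifnot(inherits(result, "decontam_result"),
            inherits(table, "feature_table"))
  if (!identical(sort(names(truth$origin)), sort(rownames(table$counts))))
    stop("feature sets of truth and table do not match")
  origin <- truth$origin[rownames(table$counts)]
  samples <- colnames(result$verdicts)
  counts <- table$counts[, samples, drop = FALSE]
  rejected <- result$verdicts == "rejected"
  by_origin <- function(org, mask = NULL) {
    m <- counts * (origin == org)
    if (!is.null(mask)) m <- m * mask
    colSums(m)
  }
  contaminant_reads <- by_origin("contaminant_only")
  true_reads <- by_origin("true_only")
  shared_reads <- by_origin("shared")
  data.frame(
    sample_id = samples,
    contaminant_reads = contaminant_reads,
    contaminant_rejected_frac = ifelse(contaminant_reads > 0,
      by_origin("contaminant_only", rejected) / contaminant_reads, NA),
    true_reads = true_reads,
    true_retained_frac = ifelse(true_reads > 0,
      1 - by_origin("true_only", rejected) / true_reads, NA),
    shared_reads = shared_reads,
    shared_rejected_frac = ifelse(shared_reads > 0,
      by_origin("shared", rejected) / shared_reads, NA),
    shared_accepted_frac = ifelse(shared_reads > 0,
      by_origin("shared", result$verdicts == "accepted_shared") /
        shared_reads, NA),
    row.names = NULL, stringsAsFactors = FALSE)
}
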