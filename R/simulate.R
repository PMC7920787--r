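#' Default community-simulation configuration
#'
#' Returns a configuration for [simulate_events()] that emulates two
#' wintering seasons' worth of daily selection events at four sub-lakes
#' (two managed, two unmanaged). Managed (R1) strata get higher per-species
#' inclusion probabilities and abundance means than unmanaged (R2) strata,
#' habitats follow the observed richness gradient (mudflat > shallow water >
#' grassland > bare ground ~ deep water), counts are negative-binomial, and
#' guild-mates share a loading on a single event-level log-normal latent
#' factor so that their abundance columns are positively correlated.
#'
#' @param catalog A validated species catalog.
#' @param n_days Number of simulated days (one selection event per site per
#'   day). Default 150, one wintering season (mid-October to mid-March).
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   event table exactly.
#' @return A list of class `sban_sim_config`. Fields:
#'   `catalog`, `n_days`, `start_date`, `sites` (data.frame `site_id`,
#'   `regime`), `habitat_suitability` and `abundance_mean` (data.frames keyed
#'   by `regime`, `habitat`, `species_id`), `dispersion` (negative-binomial
#'   shape), `activity_split` (probability an individual forages rather than
#'   roosts), `behavior_rates` (named vector over competition/aggression/
#'   courtship), `loadings` (data.frame `factor_id`, `node`, `loading`), and
#'   `seed`.
#' @export
make_default_config <- function(catalog, n_days = 150, seed = 1L) {
  habitat_p <- c(BG = 0.15, DW = 0.15, GL = 0.30, SW = 0.45, MF = 0.55)
  habitat_mu <- c(BG = 5, DW = 8, GL = 15, SW = 25, MF = 30)
  grid <- expand.grid(regime = SBAN_REGIMES, habitat = SBAN_HABITATS,
                      species_id = catalog$species_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  r1 <- grid$regime == "R1"
  suit <- grid
  suit$p_include <- ifelse(r1, habitat_p[grid$habitat],
                           0.6 * habitat_p[grid$habitat])
  mu <- grid
  mu$mean <- ifelse(r1, habitat_mu[grid$habitat],
                    0.5 * habitat_mu[grid$habitat])
  guild_loading <- c(G1 = 0.40, G2 = 0.50, G3 = 0.45, G4 = 0.30, G5 = 0.35)
  activity_nodes <- expand.grid(species_id = catalog$species_id,
                                behavior_class = c("forage", "roost"),
                                KEEP.OUT.ATTRS = FALSE,
                                stringsAsFactors = FALSE)
  loadings <- data.frame(
    factor_id = "guild",
    node = paste(activity_nodes$species_id, activity_nodes$behavior_class,
                 sep = ":"),
    loading = guild_loading[catalog$guild[match(activity_nodes$species_id,
                                                catalog$species_id)]],
    stringsAsFactors = FALSE
  )
  config <- list(
    catalog = catalog,
    n_days = as.integer(n_days),
    start_date = "2016-10-15",
    sites = data.frame(site_id = c("L1", "L2", "L3", "L4"),
                       regime = c("R1", "R1", "R2", "R2"),
                       stringsAsFactors = FALSE),
    habitat_suitability = suit,
    abundance_mean = mu,
    dispersion = 5,
    activity_split = 0.7,
    behavior_rates = c(competition = 0.10, aggression = 0.05,
                       courtship = 0.02),
    loadings = loadings,
    seed = as.integer(seed)
  )
  class(config) <- "sban_sim_config"
  validate_sim_config(config)
}

#' Validate a simulation configuration
#'
#' @param config An `sban_sim_config` list.
#' @return `config`, invisibly classed, after checking field domains.
#' @export
validate_sim_config <- function(config) {
  chk <- function(ok, field) {
    if (!ok) stop("invalid simulation config field: ", field, call. = FALSE)
  }
  chk(is.data.frame(config$catalog) && nrow(config$catalog) > 0, "catalog")
  chk(is.numeric(config$n_days) && config$n_days >= 1, "n_days")
  chk(is.data.frame(config$sites) &&
        all(config$sites$regime %in% SBAN_REGIMES), "sites")
  chk(all(config$habitat_suitability$p_include >= 0 &
            config$habitat_suitability$p_include <= 1), "habitat_suitability")
  chk(all(config$abundance_mean$mean >= 0), "abundance_mean")
  chk(is.numeric(config$dispersion) && config$dispersion > 0, "dispersion")
  chk(config$activity_split >= 0 && config$activity_split <= 1,
      "activity_split")
  chk(all(sort(names(config$behavior_rates)) ==
            sort(c("competition", "aggression", "courtship"))) &&
        all(config$behavior_rates >= 0 & config$behavior_rates <= 1),
      "behavior_rates")
  chk(is.data.frame(config$loadings) &&
        all(c("factor_id", "node", "loading") %in% names(config$loadings)),
      "loadings")
  chk(is.numeric(config$seed), "seed")
  config
}

# Per-event multiplicative factor for each node: exp(sum_k l_k f_k - sum l^2/2).
# The -l^2/2 correction keeps E[exp(.)] = 1 so marginal means are unchanged.
node_factor_matrix <- function(loadings, n_events) {
  factors <- unique(loadings$factor_id)
  nodes <- unique(loadings$node)
  if (length(nodes) == 0 || length(factors) == 0) {
    return(matrix(1, nrow = n_events, ncol = 0))
  }
  L <- matrix(0, nrow = length(nodes), ncol = length(factors),
              dimnames = list(nodes, factors))
  L[cbind(match(loadings$node, nodes), match(loadings$factor_id, factors))] <-
    loadings$loading
  f <- matrix(stats::rnorm(n_events * length(factors)),
              nrow = n_events, ncol = length(factors))
  scale <- exp(f %*% t(L) - rep(rowSums(L^2) / 2, each = n_events))
  colnames(scale) <- nodes
  scale
}

#' Simulate daily selection events
#'
#' One selection event per site per day. Within an event, each species is
#' included in each habitat independently with its configured inclusion
#' probability; an included species' foraging and roosting counts are drawn
#' from independent negative-binomial distributions whose means are the
#' configured stratum mean split by `activity_split` and scaled by the
#' node's event-level log-normal latent factor (mean-preserving). The three
#' short-term behavior counts are drawn binomially from the species' total
#' count with the configured rates (also factor-scaled, capped at 1), so a
#' behavior count can never exceed the abundance that produced it. Zero-count
#' rows are omitted, as a video observer records nothing for them.
#'
#' @param config An `sban_sim_config`, e.g. from [make_default_config()].
#' @return A validated observation-event data.frame.
#' @export
simulate_events <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  dates <- as.character(as.Date(config$start_date) + seq_len(config$n_days) - 1)
  sites <- config$sites
  species <- config$catalog$species_id
  behaviors <- c("competition", "aggression", "courtship")

  # frame: one row per (site, day, habitat, species)
  frame <- expand.grid(day = seq_len(config$n_days),
                       site_idx = seq_len(nrow(sites)),
                       habitat = SBAN_HABITATS,
                       species_id = species,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  frame$site_id <- sites$site_id[frame$site_idx]
  frame$regime <- sites$regime[frame$site_idx]
  frame$date <- dates[frame$day]
  frame$event_id <- paste(frame$site_id, frame$date, sep = "_")
  frame$event_idx <- match(frame$event_id,
                           unique(paste(rep(sites$site_id, each = config$n_days),
                                        rep(dates, nrow(sites)), sep = "_")))
  n_events <- nrow(sites) * config$n_days

  key <- paste(frame$regime, frame$habitat, frame$species_id)
  suit <- config$habitat_suitability
  p_inc <- suit$p_include[match(key, paste(suit$regime, suit$habitat,
                                           suit$species_id))]
  mu_tab <- config$abundance_mean
  mu <- mu_tab$mean[match(key, paste(mu_tab$regime, mu_tab$habitat,
                                     mu_tab$species_id))]
  if (anyNA(p_inc) || anyNA(mu)) {
    stop("invalid simulation config field: habitat_suitability/abundance_mean ",
         "(incomplete (regime, habitat, species) coverage)", call. = FALSE)
  }

  scale <- node_factor_matrix(config$loadings, n_events)
  factor_for <- function(class) {
    lab <- paste(frame$species_id, class, sep = ":")
    out <- rep(1, nrow(frame))
    hit <- lab %in% colnames(scale)
    if (any(hit)) {
      out[hit] <- scale[cbind(frame$event_idx[hit],
                              match(lab[hit], colnames(scale)))]
    }
    out
  }

  included <- stats::runif(nrow(frame)) < p_inc
  theta <- config$dispersion
  split <- config$activity_split
  forage <- roost <- integer(nrow(frame))
  idx <- which(included)
  forage[idx] <- stats::rnbinom(length(idx), size = theta,
                                mu = mu[idx] * split * factor_for("forage")[idx])
  roost[idx] <- stats::rnbinom(length(idx), size = theta,
                               mu = mu[idx] * (1 - split) * factor_for("roost")[idx])
  total <- forage + roost

  counts <- list(forage = forage, roost = roost)
  for (b in behaviors) {
    p <- pmin(1, config$behavior_rates[[b]] * factor_for(b))
    n_b <- integer(nrow(frame))
    pos <- which(total > 0)
    n_b[pos] <- stats::rbinom(length(pos), size = total[pos], prob = p[pos])
    counts[[b]] <- n_b
  }

  rows <- lapply(SBAN_BEHAVIORS, function(b) {
    keep <- counts[[b]] > 0
    if (!any(keep)) return(NULL)
    data.frame(event_id = frame$event_id[keep], date = frame$date[keep],
               site_id = frame$site_id[keep], regime = frame$regime[keep],
               habitat = frame$habitat[keep],
               species_id = frame$species_id[keep],
               behavior_class = b, count = counts[[b]][keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(event_id = character(), date = character(),
                      site_id = character(), regime = character(),
                      habitat = character(), species_id = character(),
                      behavior_class = character(), count = integer(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$site_id, out$date, out$habitat,
                   match(out$species_id, species),
                   match(out$behavior_class, SBAN_BEHAVIORS)), ]
  validate_events(out, config$catalog)
}

#' Plant a block-correlation structure in a configuration
#'
#' Rewrites the latent-factor loadings so that, in the simulated abundance
#' matrix, node columns within each group have pairwise Pearson correlation
#' approximately `rho` while columns in different groups are approximately
#' uncorrelated; marginal means are unchanged. Each group gets its own
#' independent event-level factor; a node listed in several groups loads on
#' each of them (a "bridge" node correlated with every one of its groups).
#' The loading is solved in closed form from `rho`, the negative-binomial
#' dispersion, and the mean expected count of the group's nodes, assuming
#' fully included (probability-1) species; partial inclusion dilutes the
#' realized correlation.
#'
#' @param config An `sban_sim_config`.
#' @param groups A list of character vectors of node labels
#'   (`"species:behavior"`). Groups must not repeat a node within one group.
#' @param rho Target within-group correlation in `[0, 1)`.
#' @return The modified configuration.
#' @export
plant_block_correlation <- function(config, groups, rho) {
  validate_sim_config(config)
  if (!is.numeric(rho) || rho < 0 || rho >= 1) {
    stop("rho must lie in [0, 1)", call. = FALSE)
  }
  all_nodes <- node_labels(config$catalog)
  theta <- config$dispersion
  split <- config$activity_split
  loadings <- list()
  for (g in seq_along(groups)) {
    nodes <- groups[[g]]
    if (anyDuplicated(nodes)) {
      stop("group ", g, " repeats a node label", call. = FALSE)
    }
    bad <- setdiff(nodes, all_nodes)
    if (length(bad) > 0) {
      stop("unknown node label(s) in group ", g, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (rho == 0) next
    info <- parse_node_labels(nodes)
    mu_tab <- config$abundance_mean
    class_mean <- function(sp, cls) {
      m <- mean(mu_tab$mean[mu_tab$species_id == sp])
      if (cls == "forage") m * split
      else if (cls == "roost") m * (1 - split)
      else m * config$behavior_rates[[cls]]
    }
    M <- mean(mapply(class_mean, info$species_id, info$behavior_class))
    denom <- 1 - rho * (1 + 1 / theta)
    if (M <= 0 || denom <= 0) {
      stop("rho = ", rho, " is not attainable with dispersion ", theta,
           " and group mean ", signif(M, 3), call. = FALSE)
    }
    lambda <- sqrt(log((1 - rho + rho / M) / denom))
    loadings[[length(loadings) + 1L]] <- data.frame(
      factor_id = paste0("block", g), node = nodes, loading = lambda,
      stringsAsFactors = FALSE)
  }
  config$loadings <- if (length(loadings) > 0) {
    do.call(rbind, loadings)
  } else {
    data.frame(factor_id = character(), node = character(),
               loading = numeric(), stringsAsFactors = FALSE)
  }
  config
}
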