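## Seeded synthetic atlases and queries with known ground truth.

#' Describe a synthetic projection scenario
#'
#' A scenario fully determines (given its seed) a type-structured synthetic
#' atlas and a query drawn from it. Per-gene log2 intensities are modelled
#' as a global baseline plus a clipped Gaussian per-type effect, a smooth
#' within-type gradient, per-type marker boosts and per-metacell jitter;
#' UMIs are sampled multinomially so per-metacell totals are exact.
#'
#' @param n_types Number of cell types (including any held-out ones).
#' @param metacells_per_type Atlas metacells per type.
#' @param n_genes Total genes.
#' @param n_feature_genes Number of top-variance genes tagged as features.
#' @param umis_per_metacell Multinomial sampling depth per metacell.
#' @param baseline_log2_sd Spread of the shared per-gene baseline
#'   log2 intensity (controls the expression distribution).
#' @param type_log2_sd Spread of the per-type, per-gene log2 effect.
#' @param type_log2_max Per-type effects are clipped to this magnitude so
#'   pairwise type separations stay within a realistic fold range.
#' @param n_markers Marker genes boosted per type (disjoint across types).
#' @param marker_boost Range (log2 units) of the uniform marker boost.
#' @param n_essential Essential genes per type: the markers with the
#'   highest realized fold versus the other types.
#' @param metacell_log2_sd Per-metacell jitter, making same-type metacells
#'   distinct states.
#' @param gradient_log2_sd Spread of the per-gene within-type gradient
#'   (end-to-end drift across the type's metacells).
#' @param n_noisy_genes,n_lateral_genes Genes tagged noisy / lateral
#'   (lateral genes are drawn outside the feature set).
#' @param novel_types Type labels (e.g. `"T03"`) held out of the atlas;
#'   their metacells can still be generated as query metacells.
#' @param n_mixture_queries Number of query metacells built as convex
#'   combinations of up to `max_support` same-type atlas metacells.
#' @param max_support Maximum support size of a mixture query.
#' @param doublet_pairs Optional tibble/data.frame with columns `type_a`,
#'   `type_b`, `alpha`: query metacells mixing two types' fraction vectors
#'   as `alpha * a + (1 - alpha) * b`.
#' @param novel_metacells Number of query metacells drawn per held-out
#'   type (default: all of the type's metacells).
#' @param bias_fraction Fraction of genes given a multiplicative capture
#'   bias in the query.
#' @param bias_factor The bias factor applied to those genes.
#' @param seed Integer seed; fully determines all generated data.
#' @return A validated list of class `synth_scenario`.
#' @export
synth_scenario <- function(n_types = 8, metacells_per_type = 12,
                           n_genes = 2000, n_feature_genes = 500,
                           umis_per_metacell = 50000,
                           baseline_log2_sd = 2,
                           type_log2_sd = 1.75, type_log2_max = 3.5,
                           n_markers = 40, marker_boost = c(1.5, 3),
                           n_essential = 3,
                           metacell_log2_sd = 0.4,
                           gradient_log2_sd = 0.5,
                           n_noisy_genes = 0, n_lateral_genes = 0,
                           novel_types = character(),
                           n_mixture_queries = 0, max_support = 3,
                           doublet_pairs = NULL,
                           novel_metacells = NULL,
                           bias_fraction = 0, bias_factor = 1,
                           seed = 1) {
  sc <- list(
    n_types = as.integer(n_types),
    metacells_per_type = as.integer(metacells_per_type),
    n_genes = as.integer(n_genes),
    n_feature_genes = as.integer(n_feature_genes),
    umis_per_metacell = as.integer(umis_per_metacell),
    baseline_log2_sd = baseline_log2_sd,
    type_log2_sd = type_log2_sd,
    type_log2_max = type_log2_max,
    n_markers = as.integer(n_markers),
    marker_boost = marker_boost,
    n_essential = as.integer(n_essential),
    metacell_log2_sd = metacell_log2_sd,
    gradient_log2_sd = gradient_log2_sd,
    n_noisy_genes = as.integer(n_noisy_genes),
    n_lateral_genes = as.integer(n_lateral_genes),
    novel_types = as.character(novel_types),
    n_mixture_queries = as.integer(n_mixture_queries),
    max_support = as.integer(max_support),
    doublet_pairs = doublet_pairs,
    novel_metacells = novel_metacells,
    bias_fraction = bias_fraction,
    bias_factor = bias_factor,
    seed = as.integer(seed)
  )
  with(sc, {
    stopifnot(
      n_types >= 1, metacells_per_type >= 1, n_genes >= 10,
      n_feature_genes >= 2, n_feature_genes <= n_genes,
      umis_per_metacell >= 1, n_markers >= n_essential,
      n_markers * n_types <= n_genes,
      bias_fraction >= 0, bias_fraction <= 1, bias_factor > 0,
      seed >= 0, seed < 2^28
    )
  })
  sc$type_names <- sprintf("T%02d", seq_len(sc$n_types))
  bad <- setdiff(sc$novel_types, sc$type_names)
  if (length(bad) > 0L) {
    abort(paste0("unknown novel types: ", paste(bad, collapse = ", ")))
  }
  if (!is.null(doublet_pairs)) {
    stopifnot(all(c("type_a", "type_b", "alpha") %in% names(doublet_pairs)))
    stopifnot(
      all(doublet_pairs$alpha > 0), all(doublet_pairs$alpha < 1),
      all(doublet_pairs$type_a %in% sc$type_names),
      all(doublet_pairs$type_b %in% sc$type_names),
      all(doublet_pairs$type_a != doublet_pairs$type_b)
    )
  }
  structure(sc, class = "synth_scenario")
}

## Stream-separated seeding: profiles, atlas sampling and query sampling
## draw from distinct deterministic streams of the scenario seed.
synth_seed <- function(scenario, stream) {
  set.seed(scenario$seed * 8L + stream, kind = "Mersenne-Twister")
}

## Per-type, per-metacell true expression fractions (before multinomial
## sampling), plus marker/essential bookkeeping. Deterministic per seed.
synth_profiles <- function(scenario) {
  sc <- scenario
  synth_seed(sc, 1L)
  genes <- sprintf("g%04d", seq_len(sc$n_genes))
  mu <- rnorm(sc$n_genes, 0, sc$baseline_log2_sd)
  marker_pool <- sample.int(sc$n_genes, sc$n_markers * sc$n_types)
  markers <- split(marker_pool, rep(seq_len(sc$n_types), each = sc$n_markers))
  profiles <- list()
  type_mean_log2 <- matrix(0, sc$n_types, sc$n_genes)
  for (t in seq_len(sc$n_types)) {
    z <- rnorm(sc$n_genes, 0, sc$type_log2_sd)
    z <- pmin(pmax(z, -sc$type_log2_max), sc$type_log2_max)
    boost <- rep(0, sc$n_genes)
    boost[markers[[t]]] <-
      runif(sc$n_markers, sc$marker_boost[1], sc$marker_boost[2])
    grad <- rnorm(sc$n_genes, 0, sc$gradient_log2_sd)
    base <- mu + z + boost
    type_mean_log2[t, ] <- base + grad / 2
    pos <- if (sc$metacells_per_type == 1L) {
      0.5
    } else {
      (seq_len(sc$metacells_per_type) - 1) / (sc$metacells_per_type - 1)
    }
    m <- matrix(0, sc$metacells_per_type, sc$n_genes)
    for (k in seq_len(sc$metacells_per_type)) {
      jitter <- rnorm(sc$n_genes, 0, sc$metacell_log2_sd)
      intensity <- base + pos[[k]] * grad + jitter
      frac <- 2^intensity
      m[k, ] <- frac / sum(frac)
    }
    rownames(m) <- sprintf("%s.m%02d", sc$type_names[[t]],
                           seq_len(sc$metacells_per_type))
    colnames(m) <- genes
    profiles[[sc$type_names[[t]]]] <- m
  }
  names(markers) <- sc$type_names
  # essential genes: markers with the highest realized log2 fold over the
  # mean of the other types
  essential <- lapply(seq_len(sc$n_types), function(t) {
    others <- colMeans(2^type_mean_log2[-t, , drop = FALSE])
    fold <- type_mean_log2[t, ] - log2(others)
    idx <- markers[[t]][order(fold[markers[[t]]], decreasing = TRUE)]
    genes[idx[seq_len(sc$n_essential)]]
  })
  names(essential) <- sc$type_names
  list(genes = genes, profiles = profiles, markers = markers,
       essential = essential)
}

sample_umis <- function(fractions, depth) {
  t(apply(fractions, 1L, function(p) {
    drop(rmultinom(1L, depth, p))
  }))
}

#' Generate a synthetic reference atlas
#'
#' Samples UMIs multinomially from the scenario's per-metacell expression
#' profiles for every type not held out as novel. Feature genes are the
#' top-variance genes of the realized atlas log2 expression; essential
#' genes are each type's strongest realized markers. Identical seeds give
#' bit-identical atlases.
#'
#' @param scenario A [synth_scenario()].
#' @return A validated `mc_atlas`.
#' @export
generate_atlas <- function(scenario) {
  stopifnot(inherits(scenario, "synth_scenario"))
  sc <- scenario
  prof <- synth_profiles(sc)
  kept_types <- setdiff(sc$type_names, sc$novel_types)
  if (length(kept_types) == 0L) {
    abort("all types are held out as novel; the atlas would be empty")
  }
  synth_seed(sc, 2L)
  fr <- do.call(rbind, prof$profiles[kept_types])
  umis <- sample_umis(fr, sc$umis_per_metacell)
  dimnames(umis) <- dimnames(fr)
  e <- log2(1e-5 + umis / rowSums(umis))
  v <- apply(e, 2L, stats::var)
  feature <- prof$genes[order(v, decreasing = TRUE)[seq_len(sc$n_feature_genes)]]
  non_feature <- setdiff(prof$genes, feature)
  lateral <- head(non_feature, sc$n_lateral_genes)
  noisy <- if (sc$n_noisy_genes > 0L) {
    setdiff(prof$genes, lateral)[seq_len(sc$n_noisy_genes)]
  } else {
    character()
  }
  atlas_model(
    umis,
    types = rep(kept_types, each = sc$metacells_per_type),
    feature_genes = feature,
    noisy_genes = noisy,
    lateral_genes = lateral,
    essential_genes = prof$essential[kept_types]
  )
}

#' Generate a synthetic query with ground truth
#'
#' Builds query metacells in three flavours, in this order:
#' mixtures (convex combinations of up to `max_support` same-type atlas
#' metacell profiles with Dirichlet(1) weights), doublets
#' (`alpha * type_a + (1 - alpha) * type_b` fraction mixtures), and novel
#' metacells (profiles of held-out types absent from the atlas). An
#' optional multiplicative capture bias is then applied to a random gene
#' subset (fractions renormalized, as a real capture bias would), and UMIs
#' are sampled multinomially.
#'
#' @param scenario A [synth_scenario()].
#' @param atlas The atlas from [generate_atlas()] on the same scenario;
#'   regenerated from the seed when omitted. Mixture and doublet metacells
#'   combine the atlas's realized fraction vectors (u / N); novel
#'   metacells are drawn from the held-out latent profiles.
#' @return A list with `query` (an `mc_query`) and `truth`, itself a list
#'   of tibbles: `metacells` (kind, true type, doublet composition),
#'   `weights` (true sparse atlas weights for mixtures and doublets) and
#'   `genes` (per-gene true bias factor).
#' @export
generate_query <- function(scenario, atlas = NULL) {
  stopifnot(inherits(scenario, "synth_scenario"))
  sc <- scenario
  prof <- synth_profiles(sc)
  kept_types <- setdiff(sc$type_names, sc$novel_types)
  if (is.null(atlas)) {
    atlas <- generate_atlas(sc)
  }
  stopifnot(inherits(atlas, "mc_atlas"))
  if (!identical(colnames(atlas$umis), prof$genes)) {
    abort("atlas does not match the scenario's gene universe")
  }
  fr_atlas <- atlas$umis / rowSums(atlas$umis)
  synth_seed(sc, 3L)
  fr_rows <- list()
  meta_rows <- list()
  weight_rows <- list()
  add_row <- function(frac, kind, true_type, type_a = NA_character_,
                      type_b = NA_character_, alpha = NA_real_,
                      weights = NULL) {
    i <- length(fr_rows) + 1L
    id <- sprintf("q%03d", i)
    fr_rows[[i]] <<- frac
    meta_rows[[i]] <<- tibble::tibble(
      metacell = id, kind = kind, true_type = true_type,
      type_a = type_a, type_b = type_b, alpha = alpha
    )
    if (!is.null(weights)) {
      weight_rows[[length(weight_rows) + 1L]] <<- tibble::tibble(
        metacell = id,
        atlas_metacell = names(weights),
        weight = unname(weights)
      )
    }
  }
  ## mixtures of up to max_support same-type metacells
  if (sc$n_mixture_queries > 0L) {
    types_cycle <- rep_len(kept_types, sc$n_mixture_queries)
    for (j in seq_len(sc$n_mixture_queries)) {
      t <- types_cycle[[j]]
      k <- sample.int(sc$max_support, 1L)
      support <- sort(sample.int(sc$metacells_per_type, min(k, sc$metacells_per_type)))
      w <- rgamma(length(support), 1)
      w <- w / sum(w)
      members <- sprintf("%s.m%02d", t, support)
      p <- fr_atlas[members, , drop = FALSE]
      frac <- drop(w %*% p)
      add_row(frac, "mixture", t,
              weights = setNames(w, members))
    }
  }
  ## doublets: two-type fraction mixtures
  if (!is.null(sc$doublet_pairs) && nrow(sc$doublet_pairs) > 0L) {
    mid <- ceiling(sc$metacells_per_type / 2)
    for (j in seq_len(nrow(sc$doublet_pairs))) {
      ta <- sc$doublet_pairs$type_a[[j]]
      tb <- sc$doublet_pairs$type_b[[j]]
      al <- sc$doublet_pairs$alpha[[j]]
      ma <- sprintf("%s.m%02d", ta, mid)
      mb <- sprintf("%s.m%02d", tb, mid)
      pa <- fr_atlas[ma, ]
      pb <- fr_atlas[mb, ]
      frac <- al * pa + (1 - al) * pb
      w <- setNames(c(al, 1 - al), c(ma, mb))
      add_row(frac, "doublet", if (al >= 0.5) ta else tb,
              type_a = ta, type_b = tb, alpha = al, weights = w)
    }
  }
  ## novel metacells from held-out types
  for (t in sc$novel_types) {
    n_nov <- scenario$novel_metacells %||% sc$metacells_per_type
    for (k in seq_len(min(n_nov, sc$metacells_per_type))) {
      add_row(prof$profiles[[t]][k, ], "novel", t)
    }
  }
  if (length(fr_rows) == 0L) {
    abort("the scenario describes an empty query")
  }
  fr <- do.call(rbind, fr_rows)
  colnames(fr) <- prof$genes
  ## multiplicative capture bias, then renormalization (fractions must
  ## sum to 1, so the effective per-gene bias is bias_factor / renorm)
  bias <- rep(1, sc$n_genes)
  renorm <- rep(1, length(fr_rows))
  if (sc$bias_fraction > 0 && sc$bias_factor != 1) {
    n_bias <- round(sc$bias_fraction * sc$n_genes)
    bias_idx <- sort(sample.int(sc$n_genes, n_bias))
    bias[bias_idx] <- sc$bias_factor
    fr <- sweep(fr, 2L, bias, "*")
    renorm <- rowSums(fr)
    fr <- fr / renorm
  }
  umis <- sample_umis(fr, sc$umis_per_metacell)
  meta <- dplyr::bind_rows(meta_rows)
  meta$bias_renorm <- renorm
  dimnames(umis) <- list(meta$metacell, prof$genes)
  list(
    query = query_model(umis),
    truth = list(
      metacells = meta,
      weights = if (length(weight_rows) > 0L) {
        dplyr::bind_rows(weight_rows)
      } else {
        tibble::tibble(metacell = character(), atlas_metacell = character(),
                       weight = numeric())
      },
      genes = tibble::tibble(gene = prof$genes, bias_factor = bias)
    )
  )
}
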