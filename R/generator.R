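#' Configuration for the synthetic EHR generator
#'
#' The generator emulates the statistical structure a visit-level recommender
#' exploits, without any real clinical content: a skewed (truncated-geometric)
#' visit-count distribution, latent comorbidity topics that make diagnosis
#' codes co-occur, planted diagnosis-to-drug rules, strong prescription
#' persistence across a patient's consecutive visits, occasional noise drugs,
#' a sparse symmetric DDI network, and per-drug molecular-substructure sets
#' drawn from a shared fragment pool.
#'
#' @param n_patients number of patients.
#' @param n_diagnoses,n_procedures,n_medications vocabulary sizes.
#' @param visit_geom_p success probability of the truncated geometric visit
#'   count law, `P(N = k) proportional to (1-p)^(k-1) p`, `k = 1..max_visits`.
#'   The default 0.45 gives a mean just above 2 visits per patient with most
#'   patients at 1-2 visits and a long tail.
#' @param max_visits truncation point of the visit-count law.
#' @param n_topics number of latent comorbidity topics.
#' @param rule_strength probability that a rule drug is prescribed given its
#'   rule diagnosis is present in the visit.
#' @param persistence probability that a drug prescribed at visit t-1 recurs
#'   at visit t.
#' @param noise_rate probability that one uniformly random drug is added to a
#'   visit.
#' @param ddi_density expected fraction of unordered drug pairs that interact.
#' @param fragment_pool_size number of distinct substructure graphs shared
#'   across the medication set.
#' @param fragments_per_drug integer length-2 range (min, max) of fragments
#'   per drug.
#' @param n_atom_types number of synthetic atom types (node feature one-hot).
#' @param rules_per_diagnosis integer length-2 range of rule drugs per
#'   diagnosis.
#' @param mean_diagnoses,mean_procedures Poisson means for per-visit set
#'   sizes (diagnoses get +1 so the set is never empty; procedures may be
#'   empty).
#' @param filter_empty_medications drop visits whose medication set came out
#'   empty (the default; the model needs a non-empty target).
#' @param seed integer seed; the full triple (cohort, DDI, fragments) is
#'   reproducible from it.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 100L,
                             n_diagnoses = 50L,
                             n_procedures = 25L,
                             n_medications = 40L,
                             visit_geom_p = 0.45,
                             max_visits = 10L,
                             n_topics = 5L,
                             rule_strength = 0.9,
                             persistence = 0.7,
                             noise_rate = 0.05,
                             ddi_density = 0.1,
                             fragment_pool_size = 30L,
                             fragments_per_drug = c(1L, 3L),
                             n_atom_types = 8L,
                             rules_per_diagnosis = c(1L, 2L),
                             mean_diagnoses = 2.5,
                             mean_procedures = 1.2,
                             filter_empty_medications = TRUE,
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_diagnoses = as.integer(n_diagnoses),
              n_procedures = as.integer(n_procedures),
              n_medications = as.integer(n_medications),
              visit_geom_p = visit_geom_p, max_visits = as.integer(max_visits),
              n_topics = as.integer(n_topics), rule_strength = rule_strength,
              persistence = persistence, noise_rate = noise_rate,
              ddi_density = ddi_density,
              fragment_pool_size = as.integer(fragment_pool_size),
              fragments_per_drug = as.integer(fragments_per_drug),
              n_atom_types = as.integer(n_atom_types),
              rules_per_diagnosis = as.integer(rules_per_diagnosis),
              mean_diagnoses = mean_diagnoses,
              mean_procedures = mean_procedures,
              filter_empty_medications = isTRUE(filter_empty_medications),
              seed = as.integer(seed))
  probs <- c(visit_geom_p = cfg$visit_geom_p, rule_strength = cfg$rule_strength,
             persistence = cfg$persistence, noise_rate = cfg$noise_rate,
             ddi_density = cfg$ddi_density)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0,1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  sizes <- c(cfg$n_patients, cfg$n_diagnoses, cfg$n_procedures,
             cfg$n_medications, cfg$n_topics, cfg$fragment_pool_size,
             cfg$max_visits)
  if (any(sizes <= 0)) stop("all sizes must be strictly positive")
  if (cfg$visit_geom_p <= 0) stop("visit_geom_p must be > 0")
  if (length(cfg$fragments_per_drug) != 2L ||
      cfg$fragments_per_drug[1] < 1L ||
      cfg$fragments_per_drug[1] > cfg$fragments_per_drug[2])
    stop("fragments_per_drug must be an increasing positive range")
  structure(cfg, class = "generator_config")
}

# inverse-cdf sample of the truncated geometric visit-count law
sample_visit_counts <- function(n, p, max_visits) {
  k <- seq_len(max_visits)
  pmf <- (1 - p)^(k - 1) * p
  pmf <- pmf / sum(pmf)
  sample.int(max_visits, n, replace = TRUE, prob = pmf)
}

# topic weight matrix: member codes get weight 10, others 1; with fewer
# codes than topics some topics simply have no preferred codes
topic_weights <- function(n_topics, n_codes) {
  members <- split(sample.int(n_codes), rep_len(seq_len(n_topics), n_codes))
  w <- matrix(1, n_topics, n_codes)
  for (nm in names(members)) w[as.integer(nm), members[[nm]]] <- 10
  list(weights = w, members = members)
}

#' Generate a synthetic EHR cohort with planted structure
#'
#' Per visit: a latent topic is sampled; diagnoses and procedures are drawn
#' from topic-conditional distributions; the medication set is the union of
#' (i) the rule drugs of the drawn diagnoses, each kept with probability
#' `rule_strength`, (ii) the previous visit's drugs, each kept with
#' probability `persistence`, and (iii) with probability `noise_rate` one
#' random drug. Visits with empty medication sets are dropped by default.
#'
#' @param config a [generator_config()].
#' @return list with elements `cohort` (an `ehr_cohort`) and `truth` (a
#'   `planted_truth`: the diagnosis-to-drug rule map and topic memberships).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  local_rng(config$seed, {
    dx_codes <- sprintf("DX%03d", seq_len(config$n_diagnoses))
    px_codes <- sprintf("PX%03d", seq_len(config$n_procedures))
    rx_codes <- sprintf("RX%03d", seq_len(config$n_medications))
    vocab <- new_vocabulary(dx_codes, px_codes, rx_codes)

    # planted diagnosis -> drug rules
    rule_map <- lapply(seq_len(config$n_diagnoses), function(d) {
      k <- sample(seq.int(config$rules_per_diagnosis[1],
                          config$rules_per_diagnosis[2]), 1L)
      sort(sample.int(config$n_medications, min(k, config$n_medications)))
    })
    names(rule_map) <- dx_codes

    dx_topics <- topic_weights(config$n_topics, config$n_diagnoses)
    px_topics <- topic_weights(config$n_topics, config$n_procedures)

    counts <- sample_visit_counts(config$n_patients, config$visit_geom_p,
                                  config$max_visits)
    patients <- vector("list", config$n_patients)
    for (i in seq_len(config$n_patients)) {
      pid <- sprintf("PT%05d", i)
      topic <- sample.int(config$n_topics, 1L)  # topic persists per patient
      prev_meds <- integer(0)
      visits <- list()
      for (t in seq_len(counts[i])) {
        n_dx <- min(1L + stats::rpois(1L, config$mean_diagnoses - 1),
                    config$n_diagnoses)
        dxs <- sample.int(config$n_diagnoses, n_dx,
                          prob = dx_topics$weights[topic, ])
        n_px <- min(stats::rpois(1L, config$mean_procedures),
                    config$n_procedures)
        pxs <- if (n_px > 0L)
          sample.int(config$n_procedures, n_px,
                     prob = px_topics$weights[topic, ]) else integer(0)
        rule_drugs <- unique(unlist(rule_map[dxs], use.names = FALSE))
        meds <- rule_drugs[stats::runif(length(rule_drugs)) < config$rule_strength]
        kept <- prev_meds[stats::runif(length(prev_meds)) < config$persistence]
        meds <- union(meds, kept)
        if (stats::runif(1L) < config$noise_rate)
          meds <- union(meds, sample.int(config$n_medications, 1L))
        visits[[length(visits) + 1L]] <-
          list(dx = dxs, px = pxs, rx = sort(meds))
        prev_meds <- meds
      }
      if (config$filter_empty_medications)
        visits <- Filter(function(v) length(v$rx) > 0L, visits)
      if (length(visits) == 0L) { patients[[i]] <- NULL; next }
      patients[[i]] <- new_patient(pid, lapply(seq_along(visits), function(t) {
        v <- visits[[t]]
        new_visit(pid, t, dx_codes[v$dx], px_codes[v$px], rx_codes[v$rx])
      }))
    }
    patients <- Filter(Negate(is.null), patients)

    cohort <- new_cohort(vocab, patients, metadata = list(
      generator = "visitrx synthetic", seed = config$seed,
      params = config[setdiff(names(config), "seed")]))
    truth <- structure(list(
      rule_map = rule_map,
      topic_members = list(diagnosis = dx_topics$members,
                           procedure = px_topics$members)),
      class = "planted_truth")
    list(cohort = cohort, truth = truth)
  })
}

#' Generate a random symmetric DDI matrix
#'
#' Each unordered medication pair interacts independently with probability
#' `ddi_density`; the diagonal is zero.
#'
#' @param config a [generator_config()] (only `n_medications` and
#'   `ddi_density` are used).
#' @param seed integer seed; defaults to `config$seed + 1`.
#' @return binary symmetric `|M| x |M|` matrix of class `ddi_matrix`.
#' @export
generate_ddi <- function(config, seed = config$seed + 1L) {
  m <- config$n_medications
  codes <- sprintf("RX%03d", seq_len(m))
  mat <- matrix(0L, m, m, dimnames = list(codes, codes))
  local_rng(seed, {
    up <- which(upper.tri(mat))
    hits <- up[stats::runif(length(up)) < config$ddi_density]
    mat[hits] <- 1L
  })
  mat <- mat + t(mat)
  storage.mode(mat) <- "integer"
  structure(mat, class = c("ddi_matrix", class(mat)))
}

# random connected simple graph: spanning tree + extra edges
random_fragment_graph <- function(n_nodes, n_atom_types) {
  edges <- if (n_nodes > 1L)
    cbind(2:n_nodes, vapply(2:n_nodes, function(i) sample.int(i - 1L, 1L),
                            integer(1)))
  else matrix(integer(0), 0, 2)
  n_extra <- stats::rbinom(1L, n_nodes, 0.2)
  if (n_extra > 0L && n_nodes > 2L) {
    for (k in seq_len(n_extra)) {
      ij <- sort(sample.int(n_nodes, 2L))
      edges <- rbind(edges, ij)
    }
    edges <- unique(edges)
    # drop accidental duplicates of tree edges in either orientation
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  atom_type <- sample.int(n_atom_types, n_nodes, replace = TRUE)
  new_molecule_graph(n_nodes, edges, atom_type = atom_type,
                     n_atom_types = n_atom_types)
}

#' Generate a synthetic per-drug fragment library
#'
#' Builds a fixed pool of small random connected graphs (3-12 nodes, one-hot
#' atom type plus degree as node features) standing in for BRICS fragments,
#' then assigns each medication 1..k pool fragments. Fragments are shared
#' across drugs (pool semantics), mirroring how distinct substructures are
#' pooled across a real medication set.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; defaults to `config$seed + 2`.
#' @return object of class `fragment_library`: `pool` (list of
#'   `molecule_graph`), `drug_fragments` (per-medication integer vectors of
#'   pool indices), `feature_dim`, `n_atom_types`.
#' @export
generate_fragment_library <- function(config, seed = config$seed + 2L) {
  local_rng(seed, {
    pool <- lapply(seq_len(config$fragment_pool_size), function(i)
      random_fragment_graph(sample(3:12, 1L), config$n_atom_types))
    rng <- config$fragments_per_drug
    drug_fragments <- lapply(seq_len(config$n_medications), function(d) {
      k <- sample(seq.int(rng[1], rng[2]), 1L)
      sort(sample.int(config$fragment_pool_size, min(k, config$fragment_pool_size)))
    })
    names(drug_fragments) <- sprintf("RX%03d", seq_len(config$n_medications))
    structure(list(pool = pool, drug_fragments = drug_fragments,
                   feature_dim = config$n_atom_types + 1L,
                   n_atom_types = config$n_atom_types),
              class = "fragment_library")
  })
}

#' Write / read a fragment library as JSON
#'
#' @param library a `fragment_library`.
#' @param path file path.
#' @return `path` (write) or a `fragment_library` (read).
#' @export
write_fragment_library <- function(library, path) {
  obj <- list(schema_version = 1L, n_atom_types = library$n_atom_types,
              pool = lapply(library$pool, function(g) list(
                n_nodes = g$n_nodes,
                edges = if (nrow(g$edges)) unname(apply(g$edges, 1, as.list)) else list(),
                atom_type = as.list(g$atom_type))),
              drug_fragments = lapply(library$drug_fragments, as.list))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_fragment_library
#' @export
read_fragment_library <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = FALSE)
  n_atom_types <- obj$n_atom_types
  pool <- lapply(obj$pool, function(g) {
    edges <- if (length(g$edges))
      do.call(rbind, lapply(g$edges, function(e) c(e[[1]], e[[2]])))
    else matrix(integer(0), 0, 2)
    new_molecule_graph(g$n_nodes, edges,
                       atom_type = unlist(g$atom_type),
                       n_atom_types = n_atom_types)
  })
  drug_fragments <- lapply(obj$drug_fragments, function(v)
    as.integer(unlist(v)))
  structure(list(pool = pool, drug_fragments = drug_fragments,
                 feature_dim = n_atom_types + 1L,
                 n_atom_types = n_atom_types),
            class = "fragment_library")
}
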