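# shared fixtures, built once per session and cached; all seeded

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small planted fixture for fast unit tests
small_fixture <- function() fixture("small", function() {
  generate_counts(synthetic_spec(n_cells = 300, n_features = 120, n_types = 3,
                                 markers_per_type = 10, seed = 7))
})

small_processed <- function() fixture("small_proc", function() {
  log_transform(normalize_library_size(small_fixture()$matrix))
})

# default fixture at the full study conditions (2000 x 500, C = 4)
default_fixture <- function() fixture("default", function() {
  generate_counts(synthetic_spec(seed = 7))
})

default_processed <- function() fixture("default_proc", function() {
  log_transform(normalize_library_size(default_fixture()$matrix))
})

# separable two-type fixture: disjoint marker supports, strong effect
separable_processed <- function() fixture("sep_proc", function() {
  r <- generate_counts(synthetic_spec(n_cells = 600, n_features = 200,
                                      n_types = 2, markers_per_type = 20,
                                      effect_log2fc = 4, seed = 7))
  log_transform(normalize_library_size(r$matrix))
})

# planted four-type fixture for the explainer battery
planted_fixture <- function() fixture("planted", function() {
  generate_counts(synthetic_spec(n_cells = 600, n_features = 500, n_types = 4,
                                 markers_per_type = 20, effect_log2fc = 2,
                                 seed = 7))
})

planted_processed <- function() fixture("planted_proc", function() {
  log_transform(normalize_library_size(planted_fixture()$matrix))
})

# branching-trajectory fixture (cascade along pseudotime)
trajectory_data <- function() fixture("trajectory", function() {
  generate_trajectory_counts(
    synthetic_spec(n_cells = 600, n_features = 300, markers_per_type = 20,
                   seed = 7),
    n_branches = 2, n_bins = 2)
})

trajectory_processed <- function() fixture("trajectory_proc", function() {
  log_transform(normalize_library_size(trajectory_data()$matrix))
})

# embedding -> latent -> graph -> GAT on the separable fixture, per seed
sep_pipeline <- function(seed) fixture(paste0("sep_pipe_", seed), function() {
  m <- separable_processed()
  xi <- phate_embed(m, seed = seed, mds_max_iter = 20)
  gr <- train_grae(m, xi, train_config(seed = seed))
  g <- knn_graph(gr, 15, source = "GRAE")
  cls <- train_classifier(g, m, gat_config(seed = seed), "GAT")
  list(xi = xi, grae = gr, graph = g, model = cls$model, report = cls$report)
})

# same on the planted four-type fixture (used by the explainer battery)
planted_pipeline <- function(seed) fixture(paste0("planted_pipe_", seed), function() {
  m <- planted_processed()
  xi <- phate_embed(m, seed = seed, mds_max_iter = 20)
  gr <- train_grae(m, xi, train_config(seed = seed))
  g <- knn_graph(gr, 15, source = "GRAE")
  cls <- train_classifier(g, m, gat_config(seed = seed), "GAT")
  list(graph = g, model = cls$model, report = cls$report)
})

planted_marker_ids <- function() {
  r <- planted_fixture()
  lapply(r$truth$marker_sets, function(ix) r$matrix$feature_ids[ix])
}
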