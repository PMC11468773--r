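# Shared fixtures, built once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# the scaled study scene: 64 x 64 x 32, 30 spheres of radius 4, 60-degree
# wedge, noise at 0.7 of the signal peak-to-peak
study_scene <- function() {
  fixture("study_scene", function() render_scene(scene_spec()))
}

# quieter two-class scene used for the exploration-separability checks
two_class_scene <- function() {
  fixture("two_class_scene", function()
    render_scene(scene_spec(shape = c(64L, 64L, 32L), n_spheres = 12L,
                            n_tubes = 3L, noise_sigma = 0.1,
                            wedge_half_angle = 70, seed = 3L)))
}

two_class_pairs <- function() {
  fixture("two_class_pairs", function() {
    sc <- two_class_scene()
    gt <- sc$ground_truth
    pairs <- list()
    classes <- integer()
    for (i in seq_len(nrow(gt$spheres))) {
      pairs[[length(pairs) + 1]] <-
        extract_pair(sc$volume, NULL,
                     c(gt$spheres$x[i], gt$spheres$y[i], gt$spheres$z[i]), 32)
      classes <- c(classes, 1L)
    }
    for (tb in gt$tubes) {
      cl <- tb$centerline
      for (j in seq(1, nrow(cl), by = 25)) {
        pairs[[length(pairs) + 1]] <- extract_pair(sc$volume, NULL, cl[j, ], 32)
        classes <- c(classes, 2L)
      }
    }
    list(pairs = pairs, classes = classes)
  })
}

# tiny synthetic patch pairs for fast training-contract tests
toy_pairs <- function(n = 8, side = 16, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- matrix(rnorm(side^2), side, side)
    structure(list(P_t = m, P_s = m * 0.5 + matrix(rnorm(side^2), side, side),
                   coord = c(i, i, i), side = as.integer(side),
                   border_flagged = FALSE),
              class = "patch_pair")
  })
}

mean_cosine_margin <- function(z, classes) {
  z <- z / sqrt(rowSums(z^2))
  S <- z %*% t(z)
  same <- outer(classes, classes, "==") & upper.tri(S)
  diff <- outer(classes, classes, "!=") & upper.tri(S)
  c(within = mean(S[same]), between = mean(S[diff]))
}
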