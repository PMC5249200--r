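# Shared fixtures, built once per test run.  Coarse (0.4 mm) cup phantoms
# keep the module tests fast; the acceptance tests build their own
# finer-resolution phantoms.

std_cup <- cup_spec()

coarse_cup_volumes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      unworn <- make_cup_geometry(std_cup)
      worn <- apply_wear(unworn, wear_pattern(0.5))
      cache <<- list(
        voxel = 0.4,
        pattern = wear_pattern(0.5),
        before = voxelize(unworn, voxel_size = 0.4),
        after = voxelize(worn, voxel_size = 0.4))
    }
    cache
  }
})

coarse_cup_meshes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cv <- coarse_cup_volumes()
      cache <<- list(before = extract_surface(cv$before),
                     after = extract_surface(cv$after))
    }
    cache
  }
})

# axis-aligned unit cube as 12 consistently oriented triangles
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 face (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = 1 face (normal +z)
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  surface_model(v, f)
}

articular_region <- function(margin = 1) {
  function(v) sqrt(rowSums(v^2)) < (std_cup$inner_diameter +
                                      std_cup$outer_diameter) / 4 + margin
}
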