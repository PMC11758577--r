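# Shared fixtures: toy element tables (self-contained, closed-form physics)
# and small assemblies.  Toy materials use exaggerated densities so that a
# nanometre-scale body has appreciable optical depth.

toy_element_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- tempfile("toytables")
      make_toy_tables(list(list(z = 10, k_edge = 2, jump_ratio = 5),
                           list(z = 20, k_edge = 6, jump_ratio = 4)),
                      dir = dir)
    }
    dir
  }
})

toy_elements <- function() {
  d <- toy_element_dir()
  list(T10 = load_element_table(file.path(d, "T10.csv")),
       T20 = load_element_table(file.path(d, "T20.csv")))
}

toy_materials <- function() {
  list(vacuum = material("vacuum", 0, c(T10 = 1)),
       toy10 = material("toy10", 3000, c(T10 = 1)),
       toy20 = material("toy20", 5000, c(T20 = 1)))
}

# satellite assembly built from toy media: 80 nm host of toy10 with
# nanoparticles of toy20 in a transparent world
toy_satellite <- function(n_zno = 50, seed = 11, world_radius = 300) {
  m <- build_assembly(assembly_config("satellite", sio2_diameter = 80,
                                      n_zno = n_zno,
                                      world_radius = world_radius),
                      seed = seed)
  m$media <- c(world = "vacuum", host = "toy10", np = "toy20")
  m
}

toy_sphere <- function(radius = 40, world_radius = 200)
  single_sphere_model(radius, world_radius, "toy10", "vacuum")

expect_within <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
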