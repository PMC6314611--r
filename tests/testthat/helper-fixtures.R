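# Shared fixtures, built in code at test time.

# small climate stack + virtual species + occurrences, used across modules
make_world <- function(n = 30, vars = c("t1", "t2", "p1", "p2"), seed = 42,
                       n_occ = 200) {
  env <- simulate_climate(n, n, vars, smoothness = 4, seed = seed)
  sp <- virtual_species(env, c("t1", "p1"), optima = c(0.3, -0.2),
                        breadths = c(0.8, 1.0))
  occ <- sample_occurrences(sp, n_occ, seed = seed + 1)
  list(env = env, sp = sp, occ = occ)
}

# spherical law of cosines: independent great-circle oracle
slc_km <- function(lon1, lat1, lon2, lat2, r_km = 6371.0088) {
  to_rad <- pi / 180
  d <- sin(lat1 * to_rad) * sin(lat2 * to_rad) +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * cos((lon2 - lon1) * to_rad)
  r_km * acos(pmin(pmax(d, -1), 1))
}

# write a matrix as a one-layer ESRI ASCII stack and return the dir
write_tmp_stack <- function(layers, xmin = 0, ymax = 10, cellsize = 0.5) {
  st <- env_stack(layers, xmin = xmin, ymax = ymax, cellsize = cellsize)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_env_ascii(st, dir)
  list(stack = st, dir = dir)
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
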