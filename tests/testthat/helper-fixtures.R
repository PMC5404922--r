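# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

epitope_fixture <- function() cached("epc", make_epitope_complex)

epitope_contacts <- function() cached("con", function() {
  m <- epitope_fixture()
  map_contacts(m, select_group(m, "R", "receptor"),
               select_group(m, "H,L", "antibody"))
})

epitope_interactions <- function() cached("ix", function()
  classify_interactions(epitope_fixture(), epitope_contacts()))

epitope_profile <- function() cached("prof", function()
  contact_profile(epitope_contacts(), side = "a"))

vlen <- function(v) sqrt(sum(v^2))

# independent all-pairs neighbor scan (oracle for the cell-list search)
brute_pairs <- function(xyz_a, xyz_b, cutoff) {
  d2 <- outer(rowSums(xyz_a^2), rep(1, nrow(xyz_b))) +
    outer(rep(1, nrow(xyz_a)), rowSums(xyz_b^2)) -
    2 * xyz_a %*% t(xyz_b)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  res <- data.frame(i = hit[, 1], j = hit[, 2],
                    distance = sqrt(pmax(0, d2[hit])))
  res[order(res$i, res$j), ]
}

# closed-form accessible area of two intersecting expanded spheres
two_sphere_sasa <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  cap <- function(R, Ro) {
    h <- R - (d^2 + R^2 - Ro^2) / (2 * d)
    2 * pi * R * h
  }
  4 * pi * R1^2 - cap(R1, R2) + 4 * pi * R2^2 - cap(R2, R1)
}

interaction_kinds <- function(model, groups = c("A", "B")) {
  con <- map_contacts(model, select_group(model, groups[1]),
                      select_group(model, groups[2]))
  ix <- classify_interactions(model, con)
  sort(unique(ix$kind))
}
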