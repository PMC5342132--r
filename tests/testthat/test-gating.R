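square_gate <- function(name = "P1", lo = 0, hi = 10,
                        chans = c("CD7", "CD117")) {
  gate(name, chans[1], chans[2], rect = c(lo, hi, lo, hi))
}

test_that("a rectangle covering the data range passes every event", {
  set.seed(2)
  ev <- tiny_events(matrix(runif(200, 1, 9), ncol = 2), c("CD7", "CD117"))
  expect_true(all(apply_gate(ev, square_gate())))
  expect_equal(gated_fraction(ev, gate_set(square_gate())), 100)
})

test_that("events exactly on a region boundary are inside", {
  ev <- tiny_events(rbind(c(0, 5), c(10, 5), c(5, 0), c(5, 10), c(11, 5)),
                    c("X", "Y"))
  rect <- gate("R", "X", "Y", rect = c(0, 10, 0, 10))
  expect_identical(apply_gate(ev, rect), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  tri <- gate("T", "X", "Y", polygon = rbind(c(0, 0), c(10, 0), c(5, 10)))
  on_edge <- tiny_events(rbind(c(5, 0),        # on the base edge
                               c(2.5, 5),      # on the left edge
                               c(0, 0),        # vertex
                               c(5, 11)),      # outside
                         c("X", "Y"))
  expect_identical(apply_gate(on_edge, tri), c(TRUE, TRUE, TRUE, FALSE))
})

test_that("polygon membership agrees with an independent winding-number check", {
  poly <- rbind(c(2, 1), c(9, 2), c(8, 7), c(5, 9), c(1, 6))  # convex-ish pentagon
  star <- rbind(c(5, 0), c(6.2, 3.5), c(10, 3.5), c(7, 6), c(8, 10),
                c(5, 7.8), c(2, 10), c(3, 6), c(0, 3.5), c(3.8, 3.5))  # concave
  set.seed(99)
  px <- runif(1000, -1, 11)
  py <- runif(1000, -1, 11)
  ev <- tiny_events(cbind(px, py), c("X", "Y"))
  for (v in list(poly, star)) {
    g <- gate("G", "X", "Y", polygon = v)
    expect_identical(unname(apply_gate(ev, g)),
                     oracle_point_in_polygon(px, py, v))
  }
})

test_that("gated_fraction is the AND of all gates", {
  # 4 hand-placed events; exactly one passes both gates
  ev <- tiny_events(rbind(c(1, 1), c(1, 9), c(9, 1), c(9, 9)), c("X", "Y"))
  g1 <- gate("P1", "X", "Y", rect = c(0, 5, 0, 10))   # left half
  g2 <- gate("P2", "X", "Y", rect = c(0, 10, 0, 5))   # bottom half
  expect_equal(gated_fraction(ev, gate_set(g1, g2)), 25)
  # disjoint gates on the same channels pass nothing
  d1 <- gate("A", "X", "Y", rect = c(0, 2, 0, 2))
  d2 <- gate("B", "X", "Y", rect = c(8, 10, 8, 10))
  expect_equal(gated_fraction(ev, gate_set(d1, d2)), 0)
})

test_that("AND is commutative and monotone in the number of gates", {
  set.seed(12)
  ev <- tiny_events(matrix(runif(600, 0, 10), ncol = 3), c("X", "Y", "Z"))
  g1 <- gate("P1", "X", "Y", rect = c(2, 8, 1, 9))
  g2 <- gate("P2", "Y", "Z", polygon = rbind(c(0, 0), c(10, 0), c(10, 10)))
  g3 <- gate("P3", "X", "Z", rect = c(0, 6, 3, 10))
  perms <- list(list(g1, g2, g3), list(g3, g1, g2), list(g2, g3, g1))
  fr <- vapply(perms, function(gs) gated_fraction(ev, gate_set(gs)), numeric(1))
  expect_true(all(fr == fr[1]))
  expect_gte(gated_fraction(ev, gate_set(g1)), gated_fraction(ev, gate_set(g1, g2)))
  expect_gte(gated_fraction(ev, gate_set(g1, g2)), fr[1])
})

test_that("invalid gates and unknown channels are rejected", {
  ev <- tiny_events(rbind(c(1, 1)), c("X", "Y"))
  g <- gate("P1", "X", "NOPE", rect = c(0, 1, 0, 1))
  expect_error(apply_gate(ev, g), "NOPE")
  expect_error(gate("bad", "X", "Y", rect = c(5, 1, 0, 1)), "ordered")
  expect_error(gate("bad", "X", "Y"), "exactly one")
  expect_error(gate("bad", "X", "Y", polygon = rbind(c(0, 0), c(1, 1))), ">= 3")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(gate("bad", "X", "Y", polygon = bowtie), "self-intersecting")
  expect_error(gated_fraction(event_matrix(matrix(numeric(0), 0, 2),
                                           c("X", "Y")), gate_set(g)), "empty")
})

test_that("gate sets round-trip through the YAML schema", {
  g1 <- gate("P1", "CD7", "CD117", rect = c(400, 800, 350, 750))
  g2 <- gate("P2", "SSC", "CD45", polygon = rbind(c(100, 100), c(400, 120),
                                                  c(350, 400), c(120, 380)))
  p <- withr::local_tempfile(fileext = ".yaml")
  write_gate_set(gate_set(g1, g2), p)
  back <- read_gate_set(p)
  expect_identical(length(back$gates), 2L)
  expect_equal(back$gates[[1]]$rect, g1$rect)
  expect_equal(unname(back$gates[[2]]$polygon), unname(g2$polygon))
  set.seed(6)
  ev <- tiny_events(matrix(runif(400, 0, 1000), ncol = 4),
                    c("CD7", "CD117", "SSC", "CD45"))
  expect_equal(gated_fraction(ev, back), gated_fraction(ev, gate_set(g1, g2)))
})

test_that("gates drawn on the blast support recover the spiked fraction", {
  case <- quick_patient(seed = 31, fractions = 0.2)
  fu <- case$followups[[1]]
  # rectangles around the blast population's known +/-5 SD support
  blast <- aml_blast_population()
  idx <- function(ch) match(ch, default_panel())
  rect_for <- function(chx, chy) {
    ix <- idx(chx); iy <- idx(chy)
    gate(paste0("G", chx), chx, chy,
         rect = c(blast$location[ix] - 5 * blast$spread[ix],
                  blast$location[ix] + 5 * blast$spread[ix],
                  blast$location[iy] - 5 * blast$spread[iy],
                  blast$location[iy] + 5 * blast$spread[iy]))
  }
  gs <- gate_set(rect_for("CD7", "CD117"), rect_for("SSC", "CD45"),
                 rect_for("FSC", "HLA-DR"))
  manual <- gated_fraction(fu$events, gs)
  expect_lt(abs(manual - 100 * fu$spiked_fraction), 0.2)
})
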