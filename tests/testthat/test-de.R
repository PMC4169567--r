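# hand-built probe rows: log10 profile over 13 time points, unit reference
make_probes <- function(ids, starts, ends, logprofs, strand = "+",
                        replicon = "chr", baseline = 1000) {
  tp <- sprintf("t%02d", 1:13)
  rows <- lapply(seq_along(ids), function(i) {
    inten <- baseline * 10^logprofs[[i]]
    row <- tibble::tibble(probe_id = ids[i], replicon = replicon,
                          strand = strand, start = starts[i], end = ends[i],
                          ref = baseline)
    row[, tp] <- as.list(inten)
    row
  })
  dplyr::bind_rows(rows)
}

flat13 <- rep(0, 13)

# one plus-strand call: TSSaRNA [995, 1022), cognate CDS [1000, 2600)
demo_call <- function() {
  tibble::tibble(gene_id = "G1", replicon = "chr", strand = "+",
                 tss = 995L, tssarna_end = 1021L, tssarna_length = 27L,
                 tssarna_count = 40L, tss_total_count = 55L,
                 cognate_count = 15L, distance_to_start_codon = -5L)
}

demo_annotation <- function() {
  tibble::tibble(gene_id = "G1", replicon = "chr", strand = "+",
                 cds_start = 1000L, cds_end = 2600L, length = 1600L)
}

test_that("probe selection maximizes TSSaRNA coverage without crossing the
           3' end", {
  call <- demo_call()
  probes <- make_probes(c("A", "B"), c(996L, 990L), c(1018L, 1030L),
                        list(flat13, flat13))
  expect_equal(select_probe(call, probes)$probe_id, "A")
  # no overlapping probe at all
  far <- make_probes("C", 5000L, 5020L, list(flat13))
  expect_null(select_probe(call, far))
  # equal-overlap tie goes to the more 5' probe
  tie <- make_probes(c("D", "E"), c(995L, 997L), c(1015L, 1017L),
                     list(flat13, flat13))
  expect_equal(select_probe(call, tie)$probe_id, "D")
})

test_that("relative intensity is the log10 ratio to the reference", {
  expect_equal(relative_intensity(5, 5), 0)
  expect_equal(relative_intensity(50, 5), 1)
  expect_equal(relative_intensity(2.5, 5), -0.30103, tolerance = 1e-5)
  expect_error(relative_intensity(0, 5), "positive")
})

test_that("cognate reference is the per-time-point median of probes starting
           beyond the TSSaRNA 3' end", {
  call <- demo_call()
  gene <- demo_annotation()[1, ]
  probes <- make_probes(
    c("c1", "c2", "c3"), c(1100L, 1200L, 1300L), c(1120L, 1220L, 1320L),
    list(rep(0.1, 13), rep(0.2, 13), rep(0.9, 13))
  )
  expect_equal(cognate_reference(call, probes, gene), rep(0.2, 13))
  one <- probes[2, ]
  expect_equal(cognate_reference(call, one, gene), rep(0.2, 13))
  # a probe overlapping the TSSaRNA does not qualify
  inside <- make_probes("x", 996L, 1016L, list(rep(0.5, 13)))
  expect_null(cognate_reference(call, inside, gene))
})

test_that("upstream control uses the fixed 300-bp window 120 bp away, or the
           adjacent CDS when a gene is closer than 200 bp", {
  call <- demo_call()
  ann <- demo_annotation()
  # window is [995 - 420, 995 - 120) = [575, 875)
  probes <- make_probes(
    c("in1", "in2", "edge"), c(600L, 700L, 870L), c(620L, 720L, 890L),
    list(rep(0.3, 13), rep(0.5, 13), rep(5, 13))
  )
  expect_equal(upstream_reference(call, probes, ann), rep(0.4, 13))
  # an annotated gene ending 150 bp upstream switches to its CDS probes:
  # in1/in2 also lie over that CDS, so the median is over {0.3, 0.5, 0.8}
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(
    gene_id = "G0", replicon = "chr", strand = "+",
    cds_start = 445L, cds_end = 845L, length = 400L
  ))
  probes2 <- dplyr::bind_rows(
    probes,
    make_probes("cds0", 500L, 520L, list(rep(0.8, 13)))
  )
  expect_equal(upstream_reference(call, probes2, ann2), rep(0.5, 13))
})

test_that("minus-strand upstream window mirrors downstream in genomic
           coordinates", {
  call <- demo_call()
  call$strand <- "-"
  call$tss <- 2599L
  call$tssarna_end <- 2573L
  ann <- demo_annotation()
  ann$strand <- "-"
  # window is [2600 + 120, 2600 + 420) = [2720, 3020)
  probes <- make_probes(c("u1", "out"), c(2800L, 3100L), c(2820L, 3120L),
                        list(rep(0.7, 13), rep(5, 13)), strand = "-")
  expect_equal(upstream_reference(call, probes, ann), rep(0.7, 13))
})

test_that("the V statistic at the second most different time point decides
           the call", {
  call <- demo_call()
  ann <- demo_annotation()
  base <- function(tss_prof) dplyr::bind_rows(
    make_probes("tss", 996L, 1018L, list(tss_prof)),
    make_probes("cog", 1200L, 1220L, list(flat13)),
    make_probes("up", 700L, 720L, list(flat13))
  )
  # flat V: never differentially expressed
  dc <- de_call(call, base(flat13), ann)
  expect_equal(dc$status, "ok")
  expect_false(dc$is_de)
  # |V| sorted (2.0, 1.4, ...): rank-2 value 1.4 >= 1, upstream follows V
  prof <- flat13; prof[3] <- 2.0; prof[9] <- 1.4
  dc2 <- de_call(call, base(prof), ann)
  expect_true(dc2$is_de)
  expect_equal(dc2$t_selected, 9)
  expect_equal(dc2$v_gene_selected, 1.4)
  expect_equal(dc2$direction, "up")
  # a single-point spike is never enough: rank-2 |V| = 0.9 < 1
  prof3 <- flat13; prof3[5] <- 3.0; prof3[11] <- 0.9
  dc3 <- de_call(call, base(prof3), ann)
  expect_false(dc3$is_de)
  # down-regulation passes on |V| with direction reported
  prof4 <- flat13; prof4[2] <- -1.8; prof4[7] <- -1.2
  dc4 <- de_call(call, base(prof4), ann)
  expect_true(dc4$is_de)
  expect_equal(dc4$direction, "down")
})

test_that("the upstream 2-fold criterion is evaluated at its own
           rank-selected time point", {
  call <- demo_call()
  ann <- demo_annotation()
  prof <- flat13; prof[3] <- 2.0; prof[9] <- 1.4
  # upstream region co-varies with the probe: V_up rank-2 is ~0 -> not DE
  probes <- dplyr::bind_rows(
    make_probes("tss", 996L, 1018L, list(prof)),
    make_probes("cog", 1200L, 1220L, list(flat13)),
    make_probes("up", 700L, 720L, list(prof))
  )
  dc <- de_call(call, probes, ann)
  expect_false(dc$is_de)
  expect_lt(abs(dc$v_upstream_selected), log10(2))
})

test_that("a single-time-point difference from the cognate gene is never
           called, two or more 10-fold points always pass the gene
           criterion", {
  call <- demo_call()
  ann <- demo_annotation()
  set.seed(77)
  for (i in 1:10) {
    spike <- flat13
    spike[sample(13, 1)] <- runif(1, 1, 4) * sample(c(-1, 1), 1)
    probes <- dplyr::bind_rows(
      make_probes("tss", 996L, 1018L, list(spike)),
      make_probes("cog", 1200L, 1220L, list(flat13)),
      make_probes("up", 700L, 720L, list(flat13))
    )
    expect_false(de_call(call, probes, ann)$is_de)

    multi <- flat13
    pts <- sample(13, sample(2:5, 1))
    multi[pts] <- runif(length(pts), 1, 3) * sample(c(-1, 1), 1)
    probes2 <- dplyr::bind_rows(
      make_probes("tss", 996L, 1018L, list(multi)),
      make_probes("cog", 1200L, 1220L, list(flat13)),
      make_probes("up", 700L, 720L, list(flat13))
    )
    dc <- de_call(call, probes2, ann)
    expect_gte(abs(dc$v_gene_selected), 1)
    expect_true(dc$is_de)
  }
})

test_that("permuting time-point order changes the selected index but never
           the verdict", {
  call <- demo_call()
  ann <- demo_annotation()
  set.seed(88)
  tp <- sprintf("t%02d", 1:13)
  for (i in 1:8) {
    prof <- round(runif(13, -1.6, 1.6), 2)
    probes <- dplyr::bind_rows(
      make_probes("tss", 996L, 1018L, list(prof)),
      make_probes("cog", 1200L, 1220L, list(flat13)),
      make_probes("up", 700L, 720L, list(flat13))
    )
    dc <- de_call(call, probes, ann)
    perm <- sample(13)
    probes_p <- probes
    probes_p[, tp] <- probes[, tp[perm]]
    dcp <- de_call(call, probes_p, ann)
    expect_equal(dcp$is_de, dc$is_de)
    expect_equal(abs(dcp$v_gene_selected), abs(dc$v_gene_selected))
  }
})

test_that("unevaluable calls are reported with a reason, not dropped", {
  call <- demo_call()
  ann <- demo_annotation()
  # admissible probe exists but no cognate probe beyond the 3' end
  probes <- dplyr::bind_rows(
    make_probes("tss", 996L, 1018L, list(flat13)),
    make_probes("up", 700L, 720L, list(flat13))
  )
  dc <- de_call(call, probes, ann)
  expect_equal(dc$status, "no_cognate_probe")
  expect_true(is.na(dc$is_de))
})

test_that("generator-planted DE profiles are recovered end to end", {
  g <- synth_genome(16, 55000, seed = 51)
  plants <- random_plants(g$annotation, seed = 52, frac_de = 0.5)
  syn <- synth_reads(g$annotation, plants, g$replicon_length, seed = 53)
  det <- detect_tssarnas(g$annotation, syn$reads)
  pm <- synth_probe_matrix(g$annotation, syn$truth, g$replicon_length,
                           seed = 54)
  de <- de_call_all(det$calls, pm$probes, g$annotation)
  expect_true(all(de$status == "ok"))
  truth <- syn$truth[match(de$gene_id, syn$truth$gene_id), ]
  expect_equal(de$is_de, truth$is_de)
})
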