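# Blueprint parsing, strand tracing, structure building and constraint
# emission for the 2H-AE origami family.

test_that("minimal blueprint parses and topology violations are rejected", {
  bp <- parse_blueprint(bp_text_plain())
  expect_s3_class(bp, "blueprint")
  expect_equal(nrow(bp$helices), 2L)
  expect_equal(sort(bp$crossovers$pos_a), c(5L, 15L))

  expect_error(parse_blueprint(c(bp_text_plain(), "HELIX 3 10")),
               class = "aptafret_topology")
  expect_error(parse_blueprint(c(bp_text_plain(), "XOVER 1 10 2 10")),
               class = "aptafret_topology")
  expect_error(parse_blueprint(c(bp_text_plain(), "BOGUS 1")),
               class = "aptafret_parse")
  expect_error(parse_blueprint("HELIX 1 nonsense"), class = "aptafret_parse")
})

test_that("motif layout errors: crossover overlap, motif overlap, bad anchor", {
  # kissing loop footprint across a crossover column
  expect_error(parse_blueprint(c(bp_text_plain(), "MOTIF KL180 1 5 normal")),
               class = "aptafret_layout")
  # two motifs on the same columns
  expect_error(parse_blueprint(c(bp_text_plain(), "MOTIF KL180 1 10 normal",
                                 "MOTIF KL180 1 11 normal")),
               class = "aptafret_layout")
  # cap anchored mid-helix
  expect_error(parse_blueprint(c(bp_text_plain(), "MOTIF SPINACH 1 7 normal")),
               class = "aptafret_layout")
  expect_error(parse_blueprint(c(bp_text_plain(), "MOTIF NOSUCH 1 2 normal")),
               class = "aptafret_invalid")
})

test_that("flagship blueprint matches its published layout", {
  bp <- read_blueprint(flagship_blueprint_path())
  expect_equal(bp$name, "S*5-M5")
  x <- sort(bp$crossovers$pos_a)
  # both aptamers 5 bp from the reference crossover on sister helices
  spin <- bp$motifs[bp$motifs$motif_id == "SPINACH", ]
  mang <- bp$motifs[bp$motifs$motif_id == "MANGO", ]
  expect_equal(spin$pos, 1L)
  expect_equal(x[1] - 1L, 5L)  # columns 1..5: the 5 bp stem to the crossover
  expect_equal(spin$orientation, "flipped")
  expect_equal(mang$helix, 3L - spin$helix)
  kl <- bp$motifs[bp$motifs$motif_id == "KL180", ]
  expect_true(kl$pos > x[1] && kl$pos + 1 < x[2])  # KL between the crossovers
})

test_that("trace visits every residue exactly once, with the right count", {
  lib <- motif_library()
  for (txt in list(bp_text_capped(), bp_text_flagship())) {
    bp <- parse_blueprint(txt, lib)
    tr <- trace_strand(bp, lib)
    expect_equal(nrow(tr), oracle_residue_count(bp, lib))
    dup <- tr[tr$source == "duplex", ]
    expect_equal(nrow(dup), 2L * sum(bp$helices$length_bp))
    expect_false(any(duplicated(dup[, c("helix", "column", "side")])))
    expect_equal(tr$idx, seq_len(nrow(tr)))
    # walk starts at the declared 5' end
    expect_equal(unlist(dup[1, c("helix", "column")], use.names = FALSE),
                 c(bp$five_prime$helix, bp$five_prime$pos))
  }
})

test_that("degenerate walks are rejected with informative classes", {
  lib <- motif_library()
  # no motifs at all: uncapped ends dead-end the walk
  bp <- parse_blueprint(c(bp_text_plain(), "END5 1 3 top"), lib)
  expect_error(trace_strand(bp, lib), class = "aptafret_disconnected")
  # all ends capped but no KL: the inter-crossover region forms its own cycle
  txt <- setdiff(bp_text_capped(), "MOTIF KL180 1 14 normal")
  expect_error(trace_strand(parse_blueprint(txt, lib), lib),
               class = "aptafret_disconnected")
  # 5' end inside a motif footprint
  txt <- bp_text_capped(end5 = "END5 1 14 top")
  expect_error(trace_strand(parse_blueprint(txt, lib), lib),
               class = "aptafret_disconnected")
  # missing END5
  expect_error(trace_strand(parse_blueprint(bp_text_capped(end5 = ""), lib), lib),
               class = "aptafret_invalid")
})

test_that("secondary structure is involutive, tiered, and round-trips", {
  lib <- motif_library()
  for (txt in list(bp_text_capped(), bp_text_flagship())) {
    tr <- trace_strand(parse_blueprint(txt, lib), lib)
    ss <- build_structure(tr, lib)
    n <- ss$n
    paired <- which(ss$pair_table > 0)
    expect_true(all(ss$pair_table[ss$pair_table[paired]] == paired))
    expect_false(any(ss$pair_table[paired] == paired))
    expect_equal(nchar(ss$dot_bracket), n)
    # independent stack parser reproduces the pair table
    expect_equal(oracle_parse_db(ss$dot_bracket), ss$pair_table)
    # kissing-loop pairs sit on tier 2
    expect_equal(sum(ss$tier == 2L) / 2, 6)
    # no-KL control: hairpins retained, loop-loop pairs removed
    ss0 <- build_structure(tr, lib, kissing = FALSE)
    expect_equal(sum(ss0$tier == 2L), 0L)
    expect_equal(sum(ss0$pair_table > 0) + 12L, sum(ss$pair_table > 0))
  }
})

test_that("tetraloop hairpin yields the canonical stem-loop bracket shape", {
  # one-helix-pair equivalent: a short capped tile still shows the
  # ((((....)))) shape locally around each UUCG cap
  lib <- motif_library()
  tr <- trace_strand(parse_blueprint(bp_text_capped(), lib), lib)
  ss <- build_structure(tr, lib)
  expect_match(ss$dot_bracket, "\\(\\(\\(\\(....\\)\\)\\)\\)")
})

test_that("constraints carry GGGAGA, complementary partners and GC locks", {
  lib <- motif_library()
  bp <- parse_blueprint(bp_text_flagship(), lib)
  tr <- trace_strand(bp, lib)
  ss <- build_structure(tr, lib)
  cs <- emit_constraints(tr, ss, lib)
  expect_equal(cs$n, ss$n)
  expect_equal(substr(cs$string, 1, 6), "GGGAGA")
  # partners of the initiation bases are fixed complementary
  comp <- c(G = "C", A = "U")
  for (i in 1:6) {
    j <- ss$pair_table[i]
    expect_equal(cs$chars[j], unname(comp[cs$chars[i]]))
  }
  # one G-C lock at column x+1 on each helix at each crossover
  locks <- which(cs$source == "gc_lock")
  expect_equal(length(locks), 8L)  # 4 pairs
  expect_setequal(unique(cs$chars[locks]), c("G", "C"))
  dup <- tr[tr$source == "duplex", ]
  lock_cols <- sort(unique(dup$column[dup$idx %in% locks]))
  expect_equal(lock_cols, sort(bp$crossovers$pos_a) + 1L)
  # conserved motif bases present verbatim
  expect_match(cs$string, "GAAGGGACGGUGCGGAGAGGAGA", fixed = TRUE)
})

test_that("GU wobble designation bounds every canonical run at eight", {
  lib <- motif_library()
  for (txt in list(bp_text_capped(L = 40, x2 = 34, kl = 18),
                   bp_text_flagship())) {
    bp <- parse_blueprint(txt, lib)
    tr <- trace_strand(bp, lib)
    ss <- build_structure(tr, lib)
    cs <- emit_constraints(tr, ss, lib)
    expect_lte(oracle_max_canonical_run(bp, tr, cs, lib), 8L)
    expect_length(cs$warnings, 0L)
  }
  # a >= 2 * 9 bp free segment must carry at least floor(L/9) GU pairs
  bp <- parse_blueprint(bp_text_capped(L = 40, x2 = 34, kl = 18), lib)
  tr <- trace_strand(bp, lib)
  cs <- emit_constraints(tr, build_structure(tr, lib), lib)
  seg_gu <- cs$gu_pairs[cs$gu_pairs$helix == 2 & cs$gu_pairs$column > 5 &
                          cs$gu_pairs$column <= 34, ]
  expect_gte(nrow(seg_gu), floor(29 / 9))
})

test_that("short segments need no GU and stay warning-free", {
  lib <- motif_library()
  # segments of <= 8 bp only: rule is vacuous
  bp <- parse_blueprint(bp_text_capped(L = 16, x1 = 5, x2 = 12, kl = 8,
                                       end5 = "END5 2 7 bottom"), lib)
  tr <- trace_strand(bp, lib)
  cs <- emit_constraints(tr, build_structure(tr, lib), lib)
  expect_length(cs$warnings, 0L)
  expect_lte(nrow(cs$gu_pairs), 1L)  # only the 8-long middle could trigger
})

test_that("initiation sequence over a lock column raises a conflict", {
  lib <- motif_library()
  # END5 placed so the 4th initiation base (an A) lands on the locked
  # G-C pair at column x1+1
  bp <- parse_blueprint(bp_text_capped(end5 = "END5 2 9 bottom"), lib)
  tr <- trace_strand(bp, lib)
  ss <- build_structure(tr, lib)
  expect_error(emit_constraints(tr, ss, lib),
               class = "aptafret_constraint_conflict")
})

test_that("design files are byte-stable and round-trip", {
  out <- compile_blueprint(flagship_blueprint_path())
  txt1 <- out$design_text
  txt2 <- compile_blueprint(flagship_blueprint_path())$design_text
  expect_identical(txt1, txt2)
  lines <- strsplit(txt1, "\n")[[1]]
  expect_equal(nchar(lines[2]), nchar(lines[3]))

  path <- withr::local_tempfile(fileext = ".design")
  write_design("S*5-M5", out$structure, out$constraints, path)
  rt <- read_design(path)
  expect_equal(rt$name, "S*5-M5")
  expect_equal(rt$dot_bracket, out$structure$dot_bracket)
  expect_equal(rt$constraints, out$constraints$string)

  expect_error(write_design("", out$structure, out$constraints))
  # nupack dialect lowers W and records the wobble pairs
  nup <- write_design("x", out$structure, out$constraints, dialect = "nupack")
  expect_false(grepl("W", nup))
  expect_match(nup, "# wobble pair")
})

test_that("construct names format and parse as exact inverses", {
  expect_equal(construct_name(construct_spec(5, 5, spinach_flipped = TRUE)),
               "S*5-M5")
  expect_equal(construct_name(construct_spec(-31, 30)), "S(-31)-M30")
  p <- parse_name("S*16-M16")
  expect_equal(p$spinach_offset_bp, 16L)
  expect_equal(p$mango_offset_bp, 16L)
  expect_true(p$spinach_flipped)
  expect_equal(construct_name(parse_name("B*5-M5")), "B*5-M5")

  specs <- list(construct_spec(17, 30), construct_spec(-31, 30),
                construct_spec(6, 19, donor_motif = "BROCCOLI"),
                construct_spec(16, 16, spinach_flipped = TRUE))
  for (s in specs) {
    q <- parse_name(construct_name(s))
    expect_equal(q[c("spinach_offset_bp", "mango_offset_bp", "spinach_flipped",
                     "donor_motif")],
                 s[c("spinach_offset_bp", "mango_offset_bp", "spinach_flipped",
                     "donor_motif")])
  }
  expect_error(parse_name("S5M5"), class = "aptafret_format")
  expect_error(parse_name("Q5-M5"), class = "aptafret_format")
  expect_error(construct_spec(0, 5))
})

test_that("invader complementarity checks work on the printed strands", {
  sq <- invader_sequences()
  r1 <- invader_check(sq["invader_1"], sq["anti_invader_1"])
  expect_true(r1$is_exact_reverse_complement)
  expect_equal(r1$mismatch_count, 0L)
  # whitespace in the printed anti-invader 2 is stripped
  r2 <- invader_check("CUAGACUGAAGCUCCUUGAGGGAAGUUAG",
                      "CUAACUUCCCUCAAGGAG CUUCAGUCUAG")
  expect_true(r2$is_exact_reverse_complement)
  # a non-palindromic sequence is not its own reverse complement
  r3 <- invader_check("GGAAUC", "GGAAUC")
  expect_false(r3$is_exact_reverse_complement)
  expect_gt(r3$mismatch_count, 0L)
  expect_error(invader_check("GGAT", "AUCC"), class = "aptafret_alphabet")
})

test_that("fasta round trip preserves RNA sequences", {
  path <- withr::local_tempfile(fileext = ".fa")
  seqs <- invader_sequences()
  write_rna_fasta(seqs, path)
  back <- read_rna_fasta(path)
  expect_equal(back, seqs)
})
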