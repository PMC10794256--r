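# Seeded synthetic-data generators: profile-HMM families with known
# homology structure, module-grammar BDAs with homology-group perturbation,
# full BGC records with CDS layouts, antiSMASH-dialect GenBank and
# MIBiG-style JSON writers, and transporter layouts. All randomness is
# controlled by an explicit seed so fixtures are reproducible across
# platforms.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  expr
}

#' Generate a family of related profile HMMs
#'
#' An ancestor profile of near-point-mass columns is drawn, then each member
#' copies the ancestor and redraws each column with probability
#' `divergence`. Members therefore share at least roughly
#' `(1 - divergence)` of their columns, giving a family whose within-family
#' normalized co-emission exceeds cross-family values.
#'
#' @param labels Character vector of member labels (one profile each).
#' @param length Number of match columns in the ancestor.
#' @param divergence Per-column redraw probability in `[0, 1]`.
#' @param seed Integer seed (fixes all randomness).
#' @param letters Indices of alphabet letters the family may use (disjoint
#'   subsets give families with exactly zero cross co-emission).
#' @param purity Probability mass on the chosen letter of each column
#'   (default 1: point-mass columns).
#' @return List of [profile_hmm()] objects.
#' @export
generate_phmm_family <- function(labels, length = 8, divergence = 0.2,
                                 seed = NULL, letters = seq_along(AA_ALPHABET),
                                 purity = 1) {
  stopifnot(divergence >= 0, divergence <= 1, length >= 1,
            purity > 0, purity <= 1)
  with_seed(seed, {
    n_letters <- base::length(AA_ALPHABET)
    column <- function(letter) {
      e <- rep((1 - purity) / (n_letters - 1), n_letters)
      e[letter] <- purity
      e
    }
    anc_letters <- sample(letters, length, replace = TRUE)
    lapply(labels, function(lab) {
      my <- anc_letters
      redraw <- runif(length) < divergence
      my[redraw] <- sample(letters, sum(redraw), replace = TRUE)
      profile_hmm(lab, do.call(rbind, lapply(my, column)))
    })
  })
}

#' Write profiles as a HMMER3 text file
#'
#' Emissions are written as negative natural-log probabilities (`*` for
#' zero), the format [read_hmmer3()] parses back; insert emissions and
#' transitions are filled with uniform placeholders.
#'
#' @param hmms List of [profile_hmm()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hmmer3 <- function(hmms, path) {
  fmt <- function(p) ifelse(p <= 0, "*", sprintf("%.10f", -log(p)))
  lines <- unlist(lapply(hmms, function(h) {
    k <- nrow(h$emissions)
    na <- length(h$alphabet)
    ins <- paste(fmt(rep(1 / na, na)), collapse = "  ")
    trans <- paste(rep("0.00000", 7), collapse = "  ")
    c(sprintf("HMMER3/f [bdalign | synthetic profile]"),
      sprintf("NAME  %s", h$label),
      sprintf("LENG  %d", k),
      sprintf("ALPH  amino"),
      paste(c("HMM", h$alphabet), collapse = "          "),
      "            m->m     m->i     m->d     i->m     i->i     d->m     d->d",
      paste(c("  COMPO", fmt(h$background)), collapse = "  "),
      paste(c("       ", ins), collapse = "  "),
      paste("       ", trans),
      unlist(lapply(seq_len(k), function(i) {
        c(paste(c(sprintf("%7d", i), fmt(h$emissions[i, ])), collapse = "  "),
          paste(c("       ", ins), collapse = "  "),
          paste("       ", trans))
      })),
      "//")
  }))
  writeLines(lines, path)
  invisible(path)
}

bda_grammar <- function() {
  list(NRPS = c("Cond_LCL", "AMP_binding", "PCP"),
       modular_PKS = c("Itr_KS", "AT", "DH", "ER", "KR", "PP_bind",
                       "NAD_bind_4"),
       hybrid = c("Hyb_KS", "AT", "PP_bind"))
}

#' Generate a module-grammar BDA
#'
#' Concatenates `n_modules` copies of the class's canonical module — the
#' NRPS elongation module condensation-adenylation-carrier protein, the
#' iterative PKS module (iterative KS, acyltransferase, dehydratase,
#' enoylreductase, ketoreductase, PP-binding carrier, NAD-binding domain),
#' or the hybrid KS module — optionally preceded by an
#' adenylation-carrier starter unit and terminated by a thioesterase.
#'
#' @param class `"NRPS"`, `"modular_PKS"`, or `"hybrid"`.
#' @param n_modules Number of elongation modules (0 allowed with
#'   starter/terminator).
#' @param starter,terminator Include the starter unit / terminal
#'   thioesterase.
#' @param bgc_id Identifier for the resulting [bda()].
#' @return A [bda()].
#' @examples
#' generate_bda("NRPS", 2)$tokens
#' @export
generate_bda <- function(class = c("NRPS", "modular_PKS", "hybrid"),
                         n_modules = 2, starter = FALSE, terminator = FALSE,
                         bgc_id = paste0(class, "_", n_modules)) {
  class <- match.arg(class)
  stopifnot(n_modules >= 0)
  tokens <- c(if (starter) c("AMP_binding", "PCP"),
              rep(bda_grammar()[[class]], n_modules),
              if (terminator) "TE")
  if (!length(tokens)) stop("empty BDA: need modules, a starter or a terminator")
  bda(bgc_id, tokens)
}

#' Perturb a BDA within homology groups
#'
#' Each token is independently substituted (by another member of its
#' homology group, when the group has one), deleted, or followed by an
#' inserted random token, at the given per-token rates.
#'
#' @param x A [bda()].
#' @param sub_rate,del_rate,ins_rate Per-token rates in `[0, 1]`.
#' @param groups Homology groups (default [bda_homology_groups()]).
#' @param seed Integer seed.
#' @return The perturbed [bda()].
#' @export
perturb_bda <- function(x, sub_rate = 0.1, del_rate = 0, ins_rate = 0,
                        groups = bda_homology_groups(), seed = NULL) {
  stopifnot(sub_rate >= 0, sub_rate <= 1, del_rate >= 0, del_rate <= 1,
            ins_rate >= 0, ins_rate <= 1)
  with_seed(seed, {
    pool <- unlist(groups, use.names = FALSE)
    out <- character(0)
    for (t in x$tokens) {
      if (runif(1) < del_rate) next
      if (runif(1) < sub_rate) {
        grp <- Find(function(g) t %in% g, groups)
        alt <- setdiff(grp, t)
        if (length(alt)) t <- sample(alt, 1)
      }
      out <- c(out, t)
      if (runif(1) < ins_rate) out <- c(out, sample(pool, 1))
    }
    if (!length(out)) out <- x$tokens[1]  # never emit an empty architecture
    bda(x$bgc_id, out)
  })
}

#' Simulate full BGC records with CDS layouts
#'
#' Lays each BDA's tokens onto consecutive CDSs (up to three domains per
#' CDS, random strand) along a contig, producing records that round-trip
#' through [generate_genbank()] and [parse_antismash_genbank()]. Non-modular
#' classes get `sec_met_domain`-style calls spanning their CDS; modular
#' classes get `NRPS_PKS`-style calls at codon-aligned offsets.
#'
#' @param bdas List of [bda()] objects (one record each).
#' @param class BGC class for every record.
#' @param subclass Product label written to the region feature.
#' @param contig_length Contig length in bp.
#' @param seed Integer seed.
#' @return List of [bgc_record()] objects.
#' @export
simulate_bgc_records <- function(bdas, class = "NRPS", subclass = "NRPS",
                                 contig_length = 1e5, seed = NULL) {
  source <- if (class %in% c("NRPS", "modular_PKS")) "NRPS_PKS"
            else "sec_met_domain"
  with_seed(seed, lapply(seq_along(bdas), function(k) {
    b <- bdas[[k]]
    contig <- paste0("ctg_", b$bgc_id)
    pos <- 30000
    cds <- empty_cds_table()
    calls <- empty_domain_calls()
    i <- 1; ci <- 0
    while (i <= length(b$tokens)) {
      ci <- ci + 1
      take <- if (source == "sec_met_domain") 1L
              else min(sample(1:3, 1), length(b$tokens) - i + 1)
      toks <- b$tokens[i:(i + take - 1)]
      strand <- sample(c("+", "-"), 1)
      dom_len <- 900
      cds_len <- take * dom_len + 300
      cds_id <- sprintf("%s_cds%d", b$bgc_id, ci)
      cds_start <- pos
      cds_end <- pos + cds_len
      cds <- rbind(cds, data.frame(cds_id = cds_id, start = cds_start,
                                   end = cds_end, strand = strand,
                                   stringsAsFactors = FALSE))
      for (d in seq_along(toks)) {
        off <- (d - 1) * dom_len
        if (source == "sec_met_domain") {
          g <- c(cds_start, cds_end)
        } else if (strand == "+") {
          g <- c(cds_start + off, cds_start + off + dom_len)
        } else {
          g <- c(cds_end - off - dom_len, cds_end - off)
        }
        calls <- rbind(calls, data.frame(
          label = toks[d], cds_id = cds_id, strand = strand,
          start = g[1], end = g[2], source_feature = source,
          rank_in_cds = d - 1L, stringsAsFactors = FALSE))
      }
      pos <- cds_end + sample(200:800, 1)
      i <- i + take
    }
    rec <- bgc_record(bgc_id = b$bgc_id, contig_id = contig,
                      contig_length = contig_length, bgc_class = class,
                      subclass = subclass, region_start = min(cds$start),
                      region_end = max(cds$end), role = "candidate",
                      domains = calls, cds = cds)
    flag_contig_edge(rec)
  }))
}

#' Write BGC records as antiSMASH-dialect GenBank text
#'
#' Records sharing a `contig_id` are written into one GenBank record with a
#' `region` feature per BGC and CDS features carrying `NRPS_PKS` /
#' `sec_met_domain` qualifiers; parsing the output with
#' [parse_antismash_genbank()] recovers the regions, CDS layout and domain
#' calls.
#'
#' @param records List of [bgc_record()] objects.
#' @param path Optional output path.
#' @return Character vector of GenBank lines (invisibly when `path` given).
#' @export
generate_genbank <- function(records, path = NULL) {
  by_contig <- split(records, vapply(records, `[[`, character(1), "contig_id"))
  lines <- unlist(lapply(names(by_contig), function(contig) {
    recs <- by_contig[[contig]]
    clen <- recs[[1]]$contig_length
    out <- c(sprintf("LOCUS       %s %d bp    DNA     linear   PLN 01-JAN-2026",
                     contig, as.integer(clen)),
             sprintf("DEFINITION  synthetic contig %s.", contig),
             "FEATURES             Location/Qualifiers")
    for (ri in seq_along(recs)) {
      r <- recs[[ri]]
      out <- c(out,
               feature_line("region", r$region_start, r$region_end, "+"),
               qualifier_lines("region_number", as.character(ri)),
               unlist(lapply(r$subclass, function(p)
                 qualifier_lines("product", p))))
      for (k in seq_len(nrow(r$cds))) {
        cdsrow <- r$cds[k, ]
        out <- c(out, feature_line("CDS", cdsrow$start, cdsrow$end,
                                   cdsrow$strand),
                 qualifier_lines("locus_tag", cdsrow$cds_id))
        d <- r$domains[r$domains$cds_id == cdsrow$cds_id, , drop = FALSE]
        d <- d[order(d$rank_in_cds), , drop = FALSE]
        for (j in seq_len(nrow(d))) {
          if (d$source_feature[j] == "NRPS_PKS") {
            if (cdsrow$strand == "+") {
              aa <- c((d$start[j] - cdsrow$start) / 3 + 1,
                      (d$end[j] - cdsrow$start) / 3)
            } else {
              aa <- c((cdsrow$end - d$end[j]) / 3 + 1,
                      (cdsrow$end - d$start[j]) / 3)
            }
            out <- c(out, qualifier_lines("NRPS_PKS",
              sprintf("Domain: %s (%d-%d). E-value: 1e-10. Score: 100.0.",
                      d$label[j], as.integer(aa[1]), as.integer(aa[2]))))
          } else {
            out <- c(out, qualifier_lines("sec_met_domain",
              sprintf("%s (E-value: 1e-10, bitscore: 100.0, seeds: 10)",
                      d$label[j])))
          }
        }
      }
    }
    c(out, "ORIGIN", "//")
  }))
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

feature_line <- function(key, start, end, strand) {
  loc <- sprintf("%d..%d", as.integer(start) + 1L, as.integer(end))
  if (strand == "-") loc <- sprintf("complement(%s)", loc)
  sprintf("     %-16s%s", key, loc)
}

qualifier_lines <- function(name, value) {
  sprintf("                     /%s=\"%s\"", name, value)
}

#' Write reference records as MIBiG-style JSON
#'
#' @param entries List of lists with fields `mibig_accession`,
#'   `completeness`, `evidence`, `biosyn_class`, `subclass` (PKS synthase
#'   subclasses), `compound`, `chem_acts`, `organism_name` (optional).
#' @param dir Output directory (one `<accession>.json` per entry).
#' @return Character vector of file paths, invisibly.
#' @export
generate_mibig_json <- function(entries, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(entries, function(e) {
    j <- list(cluster = list(
      mibig_accession = e$mibig_accession,
      biosyn_class = as.list(e$biosyn_class),
      loci = list(completeness = e$completeness,
                  evidence = as.list(e$evidence)),
      compounds = list(list(compound = e$compound,
                            chem_acts = as.list(e$chem_acts)))))
    if (!is.null(e$subclass))
      j$cluster$polyketide <- list(synthases = list(list(
        subclass = as.list(e$subclass))))
    if (!is.null(e$organism_name))
      j$cluster$organism_name <- e$organism_name
    path <- file.path(dir, paste0(e$mibig_accession, ".json"))
    writeLines(jsonlite::toJSON(j, auto_unbox = TRUE, pretty = TRUE,
                                null = "null"), path)
    path
  }, character(1))
  invisible(paths)
}

#' Generate a synthetic transporter layout around BGC records
#'
#' Places transporter genes of several TCDB families around each complete
#' record: under `mode = "uniform"` genes fall uniformly over the joined
#' 5'-flank + cluster + 3'-flank span at `density` genes per kb per family;
#' under `mode = "enriched"` the density inside `enrich_region` is
#' multiplied by `enrich_factor` for the families named in
#' `enriched_families`.
#'
#' @param records Complete candidate [bgc_record()] objects.
#' @param families Character vector of TCDB family codes.
#' @param config A [region_config()].
#' @param density Genes per kb per family (default 0.1).
#' @param mode `"uniform"` or `"enriched"`.
#' @param enriched_families Families receiving the density boost.
#' @param enrich_factor Density multiplier (default 5).
#' @param enrich_region Region receiving the boost (default
#'   `"in_cluster"`).
#' @param gene_length Gene length in bp (default 400).
#' @param seed Integer seed.
#' @return Transporter annotation `data.frame`.
#' @export
generate_transporter_layout <- function(records, families,
                                        config = region_config(),
                                        density = 0.1,
                                        mode = c("uniform", "enriched"),
                                        enriched_families = families[1],
                                        enrich_factor = 5,
                                        enrich_region = "in_cluster",
                                        gene_length = 400, seed = NULL) {
  mode <- match.arg(mode)
  with_seed(seed, {
    contig <- character(0); start <- numeric(0); family <- character(0)
    for (r in records) {
      spans <- region_spans(r, config)
      for (nm in names(spans)) {
        sp <- spans[[nm]]
        width_kb <- (sp[2] - sp[1]) / 1000
        if (width_kb <= 0) next
        lambda <- rep(density * width_kb, length(families))
        if (mode == "enriched" && nm == enrich_region)
          lambda[families %in% enriched_families] <-
            lambda[families %in% enriched_families] * enrich_factor
        n <- rpois(length(families), lambda)
        if (!sum(n)) next
        contig <- c(contig, rep(r$contig_id, sum(n)))
        family <- c(family, rep(families, n))
        start <- c(start, floor(runif(sum(n), sp[1], sp[2] - 1)))
      }
    }
    out <- data.frame(
      gene_id = sprintf("t%06d", seq_along(start)), contig_id = contig,
      start = start, end = start + gene_length, tcdb_family = family,
      tcdb_superfamily = sub("^([0-9]+\\.[A-Za-z0-9]+).*", "\\1", family),
      stringsAsFactors = FALSE)
    if (nrow(out)) validate_transporter_table(out) else out
  })
}
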