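# Morpheme inventory for nomenclature-like chemical names. Multiplier
# prefixes, hydrocarbon stems and functional suffixes compose into tokens
# ("monomethyl", "ethoxy"); connector words join them into full names
# ("diethylene" is out of scope -- the grammar is deliberately small so that
# membership is regex-checkable).
.chem_prefixes <- c("mono", "di", "tri", "tetra")
.chem_stems <- c("meth", "eth", "prop", "but", "pent", "hex")
.chem_suffixes <- c("yl", "ol", "ane", "ene", "oxy")
.chem_connectors <- c("glycol", "ether", "acid", "amine", "benzene")

# English-like biomedical vocabulary for non-chemical full forms.
.biomed_words <- c(
  "growth", "factor", "receptor", "protein", "binding", "clinical",
  "response", "tumor", "necrosis", "cell", "gene", "expression", "serum",
  "plasma", "membrane", "kinase", "antibody", "disease", "syndrome",
  "chronic", "acute", "pulmonary", "cardiac", "renal", "hepatic", "neural",
  "immune", "signal", "transcription", "domain", "region", "complex",
  "pathway", "activity", "inhibitor", "agonist", "channel", "transport",
  "stress", "oxidative", "vascular", "bone", "marrow", "stem", "therapy",
  "infection", "resistance", "deficiency", "antigen", "ligand")

.compound_token_re <-
  "^(mono|di|tri|tetra)?(meth|eth|prop|but|pent|hex)(yl|ol|ane|ene|oxy)$"

# sample() without the length-1 surprise
resample <- function(x, size = 1, ...) x[sample.int(length(x), size, ...)]

#' Does a string belong to the synthetic chemical-name grammar?
#'
#' A name is grammatical when every whitespace/hyphen-separated token (after
#' stripping an optional plural 's') is either a connector word or an
#' optional multiplier prefix + stem + suffix compound, possibly carrying one
#' extra inserted character (benign variant noise).
#'
#' @param x character vector of names.
#' @param strict if TRUE, tokens must match the base grammar exactly (no
#'   variant noise tolerated). Used to validate generator output before
#'   variant corruption.
#' @return Logical vector.
#' @export
matches_chemical_grammar <- function(x, strict = TRUE) {
  token_ok <- function(tok) {
    grepl(.compound_token_re, tok) || tok %in% .chem_connectors
  }
  vapply(tolower(x), function(name) {
    toks <- strsplit(name, "[ -]+")[[1]]
    if (length(toks) == 0) return(FALSE)
    all(vapply(toks, function(tok) {
      if (token_ok(tok)) return(TRUE)
      if (strict) return(FALSE)
      # tolerate a plural 's' or one inserted character
      if (grepl("s$", tok) && token_ok(sub("s$", "", tok))) return(TRUE)
      n <- nchar(tok)
      for (i in seq_len(n)) {
        if (token_ok(paste0(substr(tok, 1, i - 1), substr(tok, i + 1, n))))
          return(TRUE)
      }
      FALSE
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

#' Generate nomenclature-like chemical names
#'
#' Each name is 2-5 lowercase tokens; every token is either a compound of an
#' optional multiplier prefix (mono/di/tri/tetra), a hydrocarbon stem
#' (meth/eth/prop/but/pent/hex) and a functional suffix (yl/ol/ane/ene/oxy),
#' or a connector word (glycol/ether/acid/amine/benzene); at least one token
#' is a compound. The single-character contrast between stems such as "eth"
#' and "meth" reproduces the property that a one-letter edit to a chemical
#' name can change the compound it denotes. Draws from the R random number
#' stream; seed with [set.seed()] for reproducibility.
#'
#' @param n number of names to generate.
#' @return Character vector of length `n`.
#' @export
generate_chemical_name <- function(n = 1) {
  vapply(seq_len(n), function(i) {
    n_tok <- resample(2:5)
    is_comp <- stats::runif(n_tok) < 0.6
    if (!any(is_comp)) is_comp[resample(seq_len(n_tok))] <- TRUE
    toks <- vapply(is_comp, function(comp) {
      if (comp) {
        pre <- if (stats::runif(1) < 0.4) resample(.chem_prefixes) else ""
        paste0(pre, resample(.chem_stems), resample(.chem_suffixes))
      } else {
        resample(.chem_connectors)
      }
    }, character(1))
    paste(toks, collapse = " ")
  }, character(1))
}

# aggregate letter distribution of the chemical morpheme inventory, with
# add-one smoothing; reference profile for frequency-balanced sampling
chem_letter_profile <- function() {
  chars <- strsplit(paste(c(.chem_prefixes, .chem_stems, .chem_suffixes,
                            .chem_connectors), collapse = ""), "")[[1]]
  counts <- table(factor(chars, levels = letters))
  (as.numeric(counts) + 1) / sum(as.numeric(counts) + 26)
}

#' Letter frequencies of a set of strings
#'
#' Counts occurrences of 'a'..'z' over all strings (other characters are
#' ignored).
#'
#' @param strings character vector.
#' @return Named integer vector of length 26.
#' @export
letter_frequencies <- function(strings) {
  chars <- strsplit(paste(tolower(strings), collapse = ""), "")[[1]]
  counts <- table(factor(chars[chars %in% letters], levels = letters))
  out <- as.integer(counts)
  names(out) <- letters
  out
}

#' Generate English-like non-chemical full forms
#'
#' Samples 2-5 tokens from a packaged biomedical word list. With
#' `match_letter_frequencies = TRUE`, words are sampled with probability
#' proportional to their per-letter likelihood under the chemical morpheme
#' letter distribution, which pulls the aggregate letter frequencies of the
#' two name classes closer together while leaving their character-sequence
#' structure distinct.
#'
#' @param n number of names.
#' @param match_letter_frequencies tilt sampling toward the chemical letter
#'   profile (default FALSE).
#' @return Character vector of length `n`.
#' @export
generate_nonchemical_name <- function(n = 1, match_letter_frequencies = FALSE) {
  wts <- if (match_letter_frequencies) {
    p <- chem_letter_profile()
    vapply(.biomed_words, function(w) {
      idx <- match(strsplit(w, "")[[1]], letters)
      exp(mean(log(p[idx])))
    }, numeric(1))
  } else rep(1, length(.biomed_words))
  vapply(seq_len(n), function(i) {
    n_tok <- resample(2:5)
    paste(resample(.biomed_words, n_tok, replace = TRUE, prob = wts),
          collapse = " ")
  }, character(1))
}

#' Same-concept spelling variants of a full form
#'
#' Produces `k` surface variants that a gold concept cluster would tolerate:
#' the name itself first, then copies modified by hyphen/space swaps, a
#' plural 's' on the final token, and at most one benign character insertion
#' (drawn from `noise_chars`) per variant, occurring with probability
#' `1 - (1 - noise_rate)^nchar(name)`. For chemical names, edits other than
#' hyphenation never touch compound (prefix+stem+suffix) tokens, so variants
#' of a concept can never collide with its one-edit near-miss neighbors.
#'
#' @param name base full form.
#' @param is_chemical restrict edits to non-compound tokens.
#' @param k number of variants, at least 1.
#' @param noise_rate per-character probability driving benign insertions.
#' @param noise_chars letters eligible for benign insertion.
#' @return Character vector of length `k`; element 1 is `name`.
#' @export
make_variants <- function(name, is_chemical, k,
                          noise_rate = 0.05,
                          noise_chars = c("e", "h", "s", "y")) {
  stopifnot(k >= 1, noise_rate >= 0, noise_rate <= 1)
  base_toks <- strsplit(name, " ")[[1]]
  nt <- length(base_toks)
  editable <- if (is_chemical) !grepl(.compound_token_re, base_toks)
              else rep(TRUE, nt)
  out <- character(k)
  out[1] <- name
  for (j in seq_len(k)[-1]) {
    toks <- base_toks
    seps <- rep(" ", max(nt - 1, 0))
    if (nt >= 2 && stats::runif(1) < 0.4)
      seps[resample(seq_len(nt - 1))] <- "-"
    if (nt >= 1 && editable[nt] && !grepl("s$", toks[nt]) &&
        stats::runif(1) < 0.3)
      toks[nt] <- paste0(toks[nt], "s")
    if (any(editable) &&
        stats::runif(1) < 1 - (1 - noise_rate)^nchar(name)) {
      ti <- resample(which(editable))
      tk <- toks[ti]
      pos <- resample(0:nchar(tk))
      ch <- resample(noise_chars)
      toks[ti] <- paste0(substr(tk, 1, pos), ch,
                         substr(tk, pos + 1, nchar(tk)))
    }
    out[j] <- paste0(toks, c(seps, ""), collapse = "")
  }
  out
}

#' One-edit different-concept neighbor of a chemical name
#'
#' Emulates pairs like "diethylene glycol monoethyl ether" versus
#' "diethylene glycol monomethyl ether": a grammatical chemical name at edit
#' distance 1-2 from the input that denotes a different concept. One compound
#' token is altered, either by the stem swap meth <-> eth (a single-character
#' insertion or deletion) or by a small suffix swap (yl <-> ol, ane <-> ene,
#' oxy -> ol).
#'
#' @param name a name produced by [generate_chemical_name()].
#' @return A different grammatical chemical name within edit distance 2.
#' @export
make_near_miss <- function(name) {
  toks <- strsplit(name, " ")[[1]]
  comp <- which(grepl(.compound_token_re, toks))
  if (length(comp) == 0)
    stop("name contains no compound token; not from the chemical grammar")
  ti <- resample(comp)
  m <- regmatches(toks[ti], regexec(.compound_token_re, toks[ti]))[[1]]
  pre <- m[2]; stem <- m[3]; suf <- m[4]
  if (stem == "meth") {
    stem <- "eth"
  } else if (stem == "eth") {
    stem <- "meth"
  } else {
    suf <- switch(suf, yl = "ol", ol = "yl", ane = "ene", ene = "ane",
                  oxy = "ol")
  }
  toks[ti] <- paste0(pre, stem, suf)
  paste(toks, collapse = " ")
}

#' Configuration of the synthetic A-pair generator
#'
#' Defaults are sized for desk-scale experiments: 300 chemical and 300
#' non-chemical concepts with on average 3 spelling variants each, collision
#' groups of on average 3 concepts per abbreviation, and a 0.4 chance that a
#' chemical concept has a one-edit near-miss neighbor, yielding on the order
#' of 10^3-10^4 candidate pairs per subset.
#'
#' @param n_concepts_chemical,n_concepts_other concept counts (>= 0).
#' @param variants_per_concept mean number of variants per concept (>= 1);
#'   realized counts are `1 + Poisson(mean - 1)`.
#' @param collision_group_size mean number of distinct base concepts sharing
#'   one abbreviation (>= 1); realized sizes are `1 + Poisson(mean - 1)`.
#' @param near_miss_rate probability that a chemical concept has a one-edit
#'   neighbor concept sharing its abbreviation.
#' @param variant_noise_rate per-character probability of benign edits within
#'   a concept's variants, see [make_variants()].
#' @param noise_chars letters used for benign insertions.
#' @param match_letter_frequencies see [generate_nonchemical_name()].
#' @param seed integer seed fixing the whole dataset.
#' @return A list with class `"generator_config"`.
#' @export
generator_config <- function(n_concepts_chemical = 300,
                             n_concepts_other = 300,
                             variants_per_concept = 3,
                             collision_group_size = 3,
                             near_miss_rate = 0.4,
                             variant_noise_rate = 0.05,
                             noise_chars = c("e", "h", "s", "y"),
                             match_letter_frequencies = FALSE,
                             seed = 1L) {
  stopifnot(n_concepts_chemical >= 0, n_concepts_other >= 0,
            variants_per_concept >= 1, collision_group_size >= 1,
            near_miss_rate >= 0, near_miss_rate <= 1,
            variant_noise_rate >= 0, variant_noise_rate <= 1,
            length(noise_chars) >= 1, all(noise_chars %in% letters),
            is.numeric(seed), length(seed) == 1)
  structure(list(n_concepts_chemical = n_concepts_chemical,
                 n_concepts_other = n_concepts_other,
                 variants_per_concept = variants_per_concept,
                 collision_group_size = collision_group_size,
                 near_miss_rate = near_miss_rate,
                 variant_noise_rate = variant_noise_rate,
                 noise_chars = noise_chars,
                 match_letter_frequencies = match_letter_frequencies,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# draw n distinct names from a generator closure
draw_unique_names <- function(n, gen) {
  out <- character(0)
  tries <- 0
  while (length(out) < n) {
    out <- unique(c(out, gen(n - length(out) + 10L)))
    tries <- tries + 1
    if (tries > 100) stop("could not draw enough distinct names")
  }
  out[seq_len(n)]
}

# partition 1..n into consecutive groups with sizes 1 + Poisson(mean - 1)
partition_sizes <- function(n, mean_size) {
  sizes <- integer(0)
  total <- 0
  while (total < n) {
    s <- 1L + stats::rpois(1, mean_size - 1)
    s <- min(s, n - total)
    sizes <- c(sizes, s)
    total <- total + s
  }
  sizes
}

#' Generate a synthetic A-pair dataset with gold concept clusters
#'
#' Builds chemical and non-chemical concepts, same-concept spelling variants,
#' one-edit near-miss chemical neighbors, and abbreviations shared by groups
#' of distinct concepts (so downstream candidate generation finds
#' collisions). Abbreviations are the token initials of a group's first
#' concept, randomly truncated and disambiguated across groups. The dataset
#' is fully reproducible from `config$seed`.
#'
#' @param config a [generator_config()].
#' @return Data frame with columns `abbreviation`, `full_form`, `concept_id`,
#'   `is_chemical` (logical).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  used_abbrevs <- character(0)
  cid <- 0L

  build_class <- function(n_concepts, chemical) {
    if (n_concepts == 0) return(NULL)
    gen <- if (chemical) generate_chemical_name else
      function(m) generate_nonchemical_name(m, config$match_letter_frequencies)
    base <- draw_unique_names(n_concepts, gen)
    neighbors <- rep(NA_character_, n_concepts)
    if (chemical && config$near_miss_rate > 0) {
      gets_nm <- stats::runif(n_concepts) < config$near_miss_rate
      for (i in which(gets_nm)) {
        for (try in 1:5) {
          nm <- make_near_miss(base[i])
          if (!nm %in% base && !nm %in% neighbors) {
            neighbors[i] <- nm
            break
          }
        }
      }
    }
    sizes <- partition_sizes(n_concepts, config$collision_group_size)
    bounds <- c(0L, cumsum(sizes))
    rows <- vector("list", length(sizes))
    for (g in seq_along(sizes)) {
      members <- (bounds[g] + 1L):bounds[g + 1L]
      names_g <- base[members]
      nm_g <- neighbors[members]
      names_g <- c(names_g, nm_g[!is.na(nm_g)])
      ab <- group_abbreviation(names_g[1], used_abbrevs)
      used_abbrevs <<- c(used_abbrevs, ab)
      grp <- lapply(names_g, function(nm) {
        cid <<- cid + 1L
        k <- 1L + stats::rpois(1, config$variants_per_concept - 1)
        data.frame(abbreviation = ab,
                   full_form = make_variants(nm, chemical, k,
                                             config$variant_noise_rate,
                                             config$noise_chars),
                   concept_id = sprintf("C%06d", cid),
                   is_chemical = chemical,
                   stringsAsFactors = FALSE)
      })
      rows[[g]] <- do.call(rbind, grp)
    }
    do.call(rbind, rows)
  }

  out <- rbind(build_class(config$n_concepts_chemical, TRUE),
               build_class(config$n_concepts_other, FALSE))
  if (is.null(out)) stop("config generates an empty dataset")
  rownames(out) <- NULL
  out
}

# token initials with random truncation, disambiguated against earlier groups
group_abbreviation <- function(name, used) {
  toks <- strsplit(name, "[ -]+")[[1]]
  initials <- paste(substr(toks, 1, 1), collapse = "")
  len <- nchar(initials)
  if (len > 2) initials <- substr(initials, 1, resample(2:len))
  ab <- initials
  k <- 1L
  while (ab %in% used) {
    ab <- paste0(initials, k)
    k <- k + 1L
  }
  ab
}
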