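#' Default synthetic mortality schedule
#'
#' Adult mortality follows a Gompertz-Makeham hazard
#' m(x) = lambda + alpha exp(beta x) for ages 5+, with separate child
#' levels m0 (<1) and m1 (1-4). Female rates are the male rates divided by
#' `sex_ratio`, so the male excess the consistency checks expect holds at
#' every age. Defaults are in the range typical of a middle-mortality
#' national population (male CDR of roughly 7-9 per 1,000 under the
#' default age structure).
#'
#' @return Named list of schedule parameters.
#' @export
default_schedule <- function() {
  list(lambda = 2e-4, alpha = 3e-5, beta = 0.095, m0 = 0.02, m1 = 0.0012, sex_ratio = 1.4)
}

#' Default synthetic cause-mix model
#'
#' Age-specific mixtures over the three broad cause groups follow the
#' classic epidemiological age pattern: communicable causes dominate in
#' childhood, injuries peak at ages 15-39, and non-communicable causes
#' dominate from age 40. Within a group, cause weights decay as 1/rank
#' (a Zipf profile), mimicking the concentration of real cause lists.
#'
#' @return List with `mixture` (tibble: age bands x group1/group2/group3).
#' @export
default_cause_model <- function() {
  list(mixture = tibble(
    age_band = c("child", "youth", "adult"),
    group1 = c(0.70, 0.20, 0.08),
    group2 = c(0.22, 0.38, 0.86),
    group3 = c(0.08, 0.42, 0.06)
  ))
}

mixture_for_band <- function(cause_model, lower) {
  band <- if (lower < 15) "child" else if (lower < 40) "youth" else "adult"
  m <- cause_model$mixture
  unlist(m[m$age_band == band, c("group1", "group2", "group3")])
}

#' Generate a synthetic population table
#'
#' Deterministic given its parameters: band counts are a largest-remainder
#' integerization of an exponential age-structure model with weights
#' proportional to band width times exp(-ageing x midpoint). Positive
#' `ageing` gives a young, monotone-declining pyramid; values near zero or
#' negative give an aged structure. Sexes are split evenly.
#'
#' @param size Total population (both sexes).
#' @param ageing Structure parameter (default 0.02).
#' @param seed Recorded for provenance (the construction is deterministic).
#' @param year Calendar year (default 2015).
#' @param open_age Open age interval lower bound (default 85).
#' @return A `codqc_population` tibble.
#' @export
generate_population <- function(size, ageing = 0.02, seed = 1L, year = 2015L, open_age = 85) {
  if (size <= 0) abort("size must be positive.", class = "codqc_input_error")
  w <- population_structure_weights(ageing, open_age)
  per_sex <- allocate_lr(round(size / 2), w$weight)
  df <- bind_rows(
    tibble(year = as.integer(year), sex = "female", age_group = w$age_group, count = per_sex),
    tibble(year = as.integer(year), sex = "male", age_group = w$age_group, count = per_sex)
  )
  new_population_table(df, open_age = open_age)
}

#' Closed-form structure weights of the population model
#'
#' @inheritParams generate_population
#' @return Tibble `age_group`, `weight` (normalized to 1).
#' @export
population_structure_weights <- function(ageing = 0.02, open_age = 85) {
  info <- age_group_info(open_age)
  width <- ifelse(is.finite(info$upper), info$upper - info$lower, 15)
  w <- width * exp(-ageing * info$midpoint)
  tibble(age_group = info$age_group, weight = w / sum(w))
}

#' Generate true (defect-free) deaths from a population
#'
#' Expected deaths per band are population times the schedule rate; counts
#' are either the rounded expectation (`mode = "deterministic"`) or Poisson
#' draws (`mode = "poisson"`). Deaths are then assigned usable ICD causes
#' from age-specific broad-group mixtures; cause eligibility respects the
#' biological edit rules (no maternal deaths outside female 10-54, no
#' perinatal causes beyond infancy, sex-specific cancers on the right sex),
#' so a defect-free dataset is fully plausible. Deterministic cause
#' allocation carries rounding residuals across age bands so that even
#' rare causes receive their proportional share globally.
#'
#' @param population A `codqc_population` tibble.
#' @param schedule Mortality schedule, see [default_schedule()].
#' @param cause_model Cause mixture, see [default_cause_model()].
#' @param seed Integer seed (used in `"poisson"` mode).
#' @param mode `"deterministic"` or `"poisson"`.
#' @param metadata Code metadata supplying the usable cause set.
#' @return List: `deaths` (a `codqc_deaths` tibble) and `truth` (a truth
#'   log used by [make_comparators()] and recovery tests).
#' @export
generate_true_deaths <- function(population, schedule = default_schedule(),
                                 cause_model = default_cause_model(),
                                 seed = 1L, mode = c("deterministic", "poisson"),
                                 metadata = load_code_metadata()) {
  mode <- match.arg(mode)
  if (schedule$m0 <= 0 || schedule$m1 <= 0 || schedule$alpha <= 0) {
    abort("Schedule rates must be positive.", class = "codqc_input_error")
  }
  open_age <- attr(population, "open_age") %||% 85
  info <- age_group_info(open_age)
  year <- population$year[1]
  if (mode == "poisson") set.seed(seed)

  # usable cause set with Zipf weights within each broad group
  usable <- as_tibble(metadata) |>
    filter(.data$usability == "usable") |>
    mutate(code = purrr::map_chr(.data$code_pattern, \(p) expand_pattern(p)[1]))
  usable <- usable |>
    group_by(.data$broad_group) |>
    mutate(weight = 1 / row_number()) |>
    ungroup()
  # Age-restricted causes (maternal, perinatal) are concentrated in few
  # strata where they are leading causes; a positional Zipf weight would
  # under-represent them, so they get a fixed within-group weight.
  rules <- default_edit_rules()
  age_restricted <- unlist(purrr::map(
    which(!is.na(rules$min_age) | !is.na(rules$max_age)),
    \(r) expand_pattern(rules$code_range[r])
  ))
  usable$weight[usable$code %in% age_restricted] <- 0.5
  elig <- cause_eligibility(usable$code, info)

  rows <- list()
  expected <- list()
  for (sx in c("male", "female")) {
    div <- if (sx == "female") schedule$sex_ratio else 1
    p <- population |> filter(.data$sex == sx)
    p <- p[match(info$age_group, p$age_group), ]
    m <- (schedule$lambda + schedule$alpha * exp(schedule$beta * info$midpoint)) / div
    m[info$age_group == "<1"] <- schedule$m0 / div
    m[info$age_group == "1-4"] <- schedule$m1 / div
    ex <- p$count * m
    d_band <- if (mode == "deterministic") as.integer(round(ex)) else rpois(length(ex), ex)
    expected[[sx]] <- tibble(sex = sx, age_group = info$age_group, rate = m, expected = ex, deaths = d_band)

    carry_grp <- rep(0, 3)
    carries <- stats::setNames(
      lapply(c("group1", "group2", "group3"), \(g) rep(0, sum(usable$broad_group == g))),
      c("group1", "group2", "group3")
    )
    for (b in seq_along(info$age_group)) {
      mix <- mixture_for_band(cause_model, info$lower[b])
      if (mode == "deterministic") {
        ac <- allocate_carry(d_band[b], mix, carry_grp)
        g_counts <- ac$counts
        carry_grp <- ac$carry
      } else {
        g_counts <- as.integer(rmultinom(1, d_band[b], mix))
      }
      for (gi in seq_along(g_counts)) {
        g <- c("group1", "group2", "group3")[gi]
        sel <- usable$broad_group == g
        w <- usable$weight[sel] * elig_mask(elig, usable$code[sel], sx, b)
        if (g_counts[gi] == 0 || sum(w) == 0) next
        if (mode == "deterministic") {
          # carry only flows between strata where a code is eligible, so
          # restricted causes take their share within their own strata
          carry_in <- carries[[g]]
          carry_in[w <= 0] <- 0
          ac <- allocate_carry(g_counts[gi], w, carry_in)
          cc <- ac$counts
          carries[[g]][w > 0] <- ac$carry[w > 0]
        } else {
          cc <- as.integer(rmultinom(1, g_counts[gi], w))
        }
        keep <- cc > 0
        if (any(keep)) {
          rows[[length(rows) + 1]] <- tibble(
            year = as.integer(year), sex = sx, age_group = info$age_group[b],
            icd_code = usable$code[sel][keep], count = cc[keep]
          )
        }
      }
    }
  }
  deaths <- new_death_table(bind_rows(rows), open_age = open_age)
  exp_tab <- bind_rows(expected)
  group_mix <- deaths |>
    as_tibble() |>
    left_join(select(usable, "code", "broad_group"), by = c(icd_code = "code")) |>
    group_by(.data$broad_group) |>
    summarise(count = sum(.data$count), .groups = "drop")
  mix_vec <- setNames(rep(0, 3), c("group1", "group2", "group3"))
  mix_vec[group_mix$broad_group] <- group_mix$count / sum(group_mix$count)

  truth <- list(
    schedule = schedule, cause_model = cause_model, seed = seed, mode = mode,
    year = as.integer(year), open_age = open_age,
    expected = exp_tab,
    total_population = sum(population$count),
    total_deaths = sum(deaths$count),
    true_cdr = 1000 * sum(deaths$count) / sum(population$count),
    true_q5_0 = true_child_q(deaths, population),
    true_group_mix = mix_vec,
    reference_cause_list = sort(usable$code),
    defects = list()
  )
  list(deaths = deaths, truth = truth)
}

# Which usable codes are admissible in which (sex, band), from the
# default edit rules; returns a lookup closure environment.
cause_eligibility <- function(codes, info) {
  rules <- default_edit_rules()
  cat3 <- codes
  n_band <- nrow(info)
  # eligibility[code, sex, band]
  arr <- array(TRUE, dim = c(length(codes), 2, n_band), dimnames = list(codes, c("male", "female"), info$age_group))
  for (r in seq_len(nrow(rules))) {
    hit <- cat3 %in% expand_pattern(rules$code_range[r])
    if (!any(hit)) next
    rs <- rules$required_sex[r]
    if (!is.na(rs)) {
      other <- setdiff(c("male", "female"), rs)
      arr[hit, other, ] <- FALSE
    }
    amin <- rules$min_age[r]
    amax <- rules$max_age[r]
    if (!is.na(amin) || !is.na(amax)) {
      out_band <- (!is.na(amax) & info$lower > amax) |
        (!is.na(amin) & is.finite(info$upper) & info$upper <= amin)
      arr[hit, , out_band] <- FALSE
    }
  }
  arr
}

elig_mask <- function(arr, codes, sex, band_index) {
  as.numeric(arr[codes, sex, band_index])
}

true_child_q <- function(deaths, population, a0 = 0.3, a1 = 1.4) {
  m0 <- sum(deaths$count[deaths$age_group == "<1"]) / sum(population$count[population$age_group == "<1"])
  m1 <- sum(deaths$count[deaths$age_group == "1-4"]) / sum(population$count[population$age_group == "1-4"])
  q1 <- m0 / (1 + (1 - a0) * m0)
  q4 <- 4 * m1 / (1 + (4 - a1) * m1)
  1 - (1 - q1) * (1 - q4)
}

#' Default defect configuration (no defects)
#'
#' @return Named list understood by [degrade()].
#' @export
default_defects <- function() {
  list(
    completeness = 1, completeness_child = NULL,
    garbage = c(0, 0, 0, 0),
    missing_age = 0, missing_sex = 0, implausible = 0,
    garbage_level_codes = c("R99", "I10", "C80", "I64")
  )
}

#' Degrade a death table with controlled quality defects
#'
#' Applies, in fixed order: (1) thinning to the requested completeness
#' (optionally with a separate, lower child completeness); (2) recoding a
#' fraction of deaths to garbage codes with the stated severity mix
#' f1..f4; (3) blanking age then sex on disjoint fractions of deaths; (4)
#' recoding a fraction of deaths to biologically implausible sex-cause
#' combinations. Recoding (not insertion) keeps totals interpretable. In
#' deterministic mode every fraction is realized exactly up to rounding;
#' in poisson mode thinning is binomial and recoding multinomial.
#'
#' @param deaths A `codqc_deaths` tibble (typically defect-free).
#' @param defect_config List as [default_defects()].
#' @param seed Integer seed (stochastic mode).
#' @param mode `"deterministic"` or `"poisson"`.
#' @param metadata Code metadata (identifies usable rows for recoding).
#' @param truth Optional truth log to append the applied defects to.
#' @return List: `deaths` (degraded), `truth` (updated truth log or the
#'   defect record when no log was supplied).
#' @export
degrade <- function(deaths, defect_config = default_defects(), seed = 1L,
                    mode = c("deterministic", "poisson"),
                    metadata = load_code_metadata(), truth = NULL) {
  mode <- match.arg(mode)
  cfg <- utils::modifyList(default_defects(), defect_config)
  fr <- c(cfg$completeness, cfg$completeness_child %||% cfg$completeness, cfg$garbage, cfg$missing_age, cfg$missing_sex, cfg$implausible)
  if (any(fr < 0 | fr > 1) || sum(cfg$garbage) > 1) {
    abort("Defect fractions must lie in [0, 1] (garbage mix summing to at most 1).",
      class = "codqc_input_error"
    )
  }
  if (mode == "poisson") set.seed(seed + 1L)
  open_age <- attr(deaths, "open_age") %||% 85
  df <- as_tibble(deaths)

  # (1) completeness thinning
  child <- df$age_group %in% c("<1", "1-4")
  thin_block <- function(d, c_frac) {
    if (nrow(d) == 0 || c_frac >= 1) {
      return(d)
    }
    if (mode == "deterministic") {
      d$count <- allocate_lr(round(c_frac * sum(d$count)), d$count)
    } else {
      d$count <- rbinom(nrow(d), d$count, c_frac)
    }
    d
  }
  c_child <- cfg$completeness_child %||% cfg$completeness
  df <- bind_rows(thin_block(df[child, ], c_child), thin_block(df[!child, ], cfg$completeness)) |>
    filter(.data$count > 0)

  # (2) garbage recoding by severity level
  usable_idx <- classify_code(df$icd_code, metadata)$usability == "usable"
  total <- sum(df$count)
  if (any(cfg$garbage > 0) && total > 0) {
    if (mode == "deterministic") {
      for (l in 1:4) {
        if (cfg$garbage[l] <= 0) next
        target <- round(cfg$garbage[l] * total)
        pool <- which(usable_idx & df$count > 0)
        moved <- allocate_lr(min(target, sum(df$count[pool])), df$count[pool])
        df$count[pool] <- df$count[pool] - moved
        add <- df[pool[moved > 0], c("year", "sex", "age_group")]
        add$icd_code <- cfg$garbage_level_codes[l]
        add$count <- moved[moved > 0]
        df <- bind_rows(df, add)
        usable_idx <- c(usable_idx, rep(FALSE, nrow(add)))
      }
    } else {
      probs <- c(1 - sum(cfg$garbage), cfg$garbage)
      pool <- which(usable_idx & df$count > 0)
      for (i in pool) {
        draw <- as.integer(rmultinom(1, df$count[i], probs))
        if (all(draw[-1] == 0)) next
        df$count[i] <- draw[1]
        for (l in which(draw[-1] > 0)) {
          df <- bind_rows(df, tibble(
            year = df$year[i], sex = df$sex[i], age_group = df$age_group[i],
            icd_code = cfg$garbage_level_codes[l], count = draw[l + 1]
          ))
        }
      }
    }
    df <- df |> filter(.data$count > 0)
  }

  # (3) blanking age, then sex on rows with known age (disjoint masses)
  blank <- function(d, frac, field) {
    total <- sum(d$count)
    if (frac <= 0 || total == 0) {
      return(d)
    }
    pool <- if (field == "sex") which(d$age_group != "unknown") else seq_len(nrow(d))
    moved <- if (mode == "deterministic") {
      allocate_lr(round(frac * total), d$count[pool])
    } else {
      rbinom(length(pool), d$count[pool], min(1, frac * total / sum(d$count[pool])))
    }
    add <- d[pool[moved > 0], ]
    add$count <- moved[moved > 0]
    add[[field]] <- "unknown"
    d$count[pool] <- d$count[pool] - moved
    bind_rows(d, add) |> filter(.data$count > 0)
  }
  df <- blank(df, cfg$missing_age, "age_group")
  df <- blank(df, cfg$missing_sex, "sex")

  # (4) implausible recoding: male deaths to cervical cancer (C53), with
  # any shortfall taken from female deaths recoded to prostate cancer (C61)
  if (cfg$implausible > 0 && sum(df$count) > 0) {
    usable_idx <- classify_code(df$icd_code, metadata)$usability == "usable"
    target <- round(cfg$implausible * sum(df$count))
    recode_to <- function(d, pool, amount, code) {
      if (amount <= 0 || length(pool) == 0) {
        return(list(d = d, done = 0))
      }
      avail <- sum(d$count[pool])
      moved <- allocate_lr(min(amount, avail), d$count[pool])
      add <- d[pool[moved > 0], c("year", "sex", "age_group")]
      add$icd_code <- code
      add$count <- moved[moved > 0]
      d$count[pool] <- d$count[pool] - moved
      list(d = bind_rows(d, add) |> filter(.data$count > 0), done = sum(moved))
    }
    pool_m <- which(usable_idx & df$sex == "male" & df$icd_code != "C53")
    r1 <- recode_to(df, pool_m, target, "C53")
    df <- r1$d
    if (r1$done < target) {
      usable_idx <- classify_code(df$icd_code, metadata)$usability == "usable"
      pool_f <- which(usable_idx & df$sex == "female" & df$icd_code != "C61")
      df <- recode_to(df, pool_f, target - r1$done, "C61")$d
    }
  }

  out <- df |>
    group_by(.data$year, .data$sex, .data$age_group, .data$icd_code) |>
    summarise(count = sum(.data$count), .groups = "drop")
  defect_record <- list(config = cfg, mode = mode, seed = seed, total_after = sum(out$count))
  if (!is.null(truth)) {
    truth$defects <- c(truth$defects, list(defect_record))
  } else {
    truth <- list(defects = list(defect_record))
  }
  list(deaths = new_death_table(out, open_age = open_age), truth = truth)
}

#' Build a comparator set from a truth log
#'
#' The comparator CDR trend, 5q0 estimate, broad-group envelope and
#' reference cause list are taken from the undegraded truth, so recovery
#' tests (and a defect-free dataset) have an exact reference: scoring
#' undegraded data against its own comparators yields completeness 1 and a
#' zero envelope delta.
#'
#' @param truth Truth log from [generate_true_deaths()].
#' @return A `codqc_comparators` object.
#' @export
make_comparators <- function(truth) {
  years <- seq(truth$year - 15, truth$year + 15, by = 5)
  new_comparators(
    cdr_trend = tibble(year = years, cdr = rep(truth$true_cdr, length(years))),
    u5mr_estimate = list(year = truth$year, value = truth$true_q5_0),
    broad_group_envelope = truth$true_group_mix,
    reference_cause_list = truth$reference_cause_list
  )
}

#' One-call synthetic dataset with known truth
#'
#' Convenience wrapper: population, true deaths, optional degradation and
#' truth-matched comparators; optionally written to a directory as
#' deaths.csv, population.csv, comparators.yaml and truth.json.
#'
#' @param seed Integer seed for all randomness.
#' @param size Population size (default 2e6).
#' @param ageing Age-structure parameter (default 0.02).
#' @param defects Defect configuration (default none).
#' @param mode `"deterministic"` or `"poisson"`.
#' @param year Calendar year.
#' @param schedule,cause_model,metadata See [generate_true_deaths()].
#' @param out_dir Optional output directory.
#' @return List: `deaths`, `population`, `comparators`, `truth`,
#'   `deaths_true`.
#' @export
simulate_dataset <- function(seed = 1L, size = 2e6, ageing = 0.02,
                             defects = default_defects(),
                             mode = c("deterministic", "poisson"),
                             year = 2015L,
                             schedule = default_schedule(),
                             cause_model = default_cause_model(),
                             metadata = load_code_metadata(),
                             out_dir = NULL) {
  mode <- match.arg(mode)
  pop <- generate_population(size, ageing = ageing, seed = seed, year = year)
  gen <- generate_true_deaths(pop, schedule, cause_model, seed = seed, mode = mode, metadata = metadata)
  deg <- degrade(gen$deaths, defects, seed = seed, mode = mode, metadata = metadata, truth = gen$truth)
  comp <- make_comparators(gen$truth)
  out <- list(
    deaths = deg$deaths, population = pop, comparators = comp,
    truth = deg$truth, deaths_true = gen$deaths
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_death_table(out$deaths, file.path(out_dir, "deaths.csv"))
    readr::write_csv(as_tibble(pop), file.path(out_dir, "population.csv"))
    write_comparators(comp, file.path(out_dir, "comparators.yaml"))
    truth_json <- out$truth
    truth_json$expected <- NULL
    jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
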