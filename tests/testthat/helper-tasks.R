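# shared builders for small tasks and a throw-away global config

local_config <- function(env = parent.frame()) {
  cfg <- read_global_config()
  cfg$work_dir <- withr::local_tempdir(.local_envir = env)
  cfg
}

one_per_job <- load_balance_config(override_one_per_job = TRUE)

stochastic_task <- function(repeat_count, t_end = 2, n_points = 5,
                            base_seed = 1, id = "stoch") {
  task_spec("stochastic_repeat", fixture_model("birth_death"),
            repeat_count = repeat_count, t_end = t_end, n_points = n_points,
            base_seed = base_seed, balance = one_per_job, task_id = id)
}

quadratic_task <- function(repeat_count = 3, algorithm = "particle_swarm",
                           id = "optrep") {
  # minimizing (k - 1)^2 over the decay model's rate constant: the target
  # A at t = 1 equals 100 * exp(-k), so |A - 100 exp(-1)| has its minimum
  # at k = 1
  task_spec("optimization_repeat", fixture_model("decay"),
            repeat_count = repeat_count, target_spec = "A",
            direction = "maximize",
            optimize_parameters = data.frame(name = "k", lower = 0.2, upper = 3),
            algorithm = algorithm,
            settings = list(swarm_size = 8, iterations = 15),
            t_end = 1, base_seed = 7, balance = one_per_job, task_id = id)
}

stub_task <- function(n, duration = 0, fail_jobs = integer(0),
                      nominal_cpu = 1, id = "stub") {
  # a raw-style bundle of sleep stubs, built directly as job documents
  task <- task_spec("raw", repeat_count = n, raw_executable = "true",
                    raw_args = "-o {out}", base_seed = 0, task_id = id)
  bundle <- split_task(task)
  bundle$jobs$document <- lapply(seq_len(n), function(i) {
    list(task_id = id, task_type = "stub", kind = "stub",
         duration = duration, nominal_cpu = nominal_cpu,
         fail = (i - 1) %in% fail_jobs,
         seed = i - 1, output = sprintf("job_%d.out", i - 1))
  })
  bundle$jobs$output_file <- sprintf("job_%d.out", seq_len(n) - 1)
  bundle
}
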