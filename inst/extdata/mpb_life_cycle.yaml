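# Mountain pine beetle life-cycle configuration.
#
# Eight stages in fixed order; each stage has a Logan-type hump-shaped
# median development-rate curve r(T), a log-normal rate-variability scale
# sigma, and a maturation threshold gamma (physiological age is scaled so
# every stage completes at 1). Cold-snap mortality (step function at
# cold_threshold on daily minimum temperature) applies only to the
# cold-sensitive stages; the larval instars cold-harden and carry none.
#
# The rate parameters below are ILLUSTRATIVE: chosen once to give
# field-realistic stage durations (egg ~10 d at 20 degC, fourth instar the
# slowest, a one-year life cycle under montane seasonal forcing), not
# fitted to rearing data. Replace psi/rho/t_base/t_max/delta per stage with
# fitted values to reproduce a specific population.
cold_threshold: -18.0
flight:
  flight_threshold: 18.3   # degC on daily maximum; flight strictly above
  settling_rate: 0.231049  # day^-1 (= ln 2 / 3: 3-day flight half-life; illustrative)
stages:
  - name: egg
    family: hump_nonlinear
    params: {psi: 0.01653, rho: 0.12, t_base: 5.0, t_max: 33.0, delta: 1.5}
    sigma: 0.20
    gamma: 1.0
    mortality: cold_step
  - name: L1
    family: hump_nonlinear
    params: {psi: 0.02066, rho: 0.12, t_base: 5.0, t_max: 33.0, delta: 1.5}
    sigma: 0.25
    gamma: 1.0
    mortality: none
  - name: L2
    family: hump_nonlinear
    params: {psi: 0.02066, rho: 0.12, t_base: 5.0, t_max: 33.0, delta: 1.5}
    sigma: 0.25
    gamma: 1.0
    mortality: none
  - name: L3
    family: hump_nonlinear
    params: {psi: 0.01653, rho: 0.12, t_base: 5.0, t_max: 33.0, delta: 1.5}
    sigma: 0.25
    gamma: 1.0
    mortality: none
  - name: L4
    family: hump_nonlinear
    params: {psi: 0.00577, rho: 0.12, t_base: 2.0, t_max: 33.0, delta: 1.5}
    sigma: 0.25
    gamma: 1.0
    mortality: none
  - name: pupa
    family: hump_nonlinear
    params: {psi: 0.01377, rho: 0.12, t_base: 5.0, t_max: 33.0, delta: 1.5}
    sigma: 0.20
    gamma: 1.0
    mortality: cold_step
  - name: teneral_adult
    family: hump_nonlinear
    params: {psi: 0.01180, rho: 0.12, t_base: 5.0, t_max: 33.0, delta: 1.5}
    sigma: 0.20
    gamma: 1.0
    mortality: cold_step
  - name: adult
    family: hump_nonlinear
    params: {psi: 0.01653, rho: 0.12, t_base: 5.0, t_max: 33.0, delta: 1.5}
    sigma: 0.15
    gamma: 1.0
    mortality: cold_step
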