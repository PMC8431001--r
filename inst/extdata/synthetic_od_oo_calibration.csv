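# Synthetic OD-stretch frequency vs O..O distance calibration knots.
# Assembled to follow the slope and range of published ice/hydrate-type
# nu(OD) <-> R(O..O) correlations (monotone, with d(nu)/dR decreasing
# towards the free-OD limit); intended as a replaceable placeholder.
# Replace with your laboratory's calibration for quantitative distances.
R_angstrom,nu_cm1
2.50,1950
2.60,2200
2.70,2360
2.76,2435
2.823,2509
2.90,2580
3.00,2630
3.10,2665
3.25,2695
3.40,2712
3.60,2727
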