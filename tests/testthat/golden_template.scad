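difference() {
  translate([-4.165000, -4.165000, 0.000000]) cube([17.080000, 8.330000, 1.400000]);
  translate([0.000000, 0.000000, 0.000000]) sphere(r = 4.165000, $fn = 48);
  translate([0.000000, 0.000000, 0.000000]) rotate([0.000000, 0.000000, 0.000000]) cylinder(h = 5.565000, r = 4.165000, $fn = 48);
  translate([8.750000, 0.000000, 2.800000]) sphere(r = 4.165000, $fn = 48);
  translate([8.750000, 0.000000, 2.800000]) rotate([0.000000, 0.000000, 0.000000]) cylinder(h = 2.765000, r = 4.165000, $fn = 48);
}
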