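<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="chain" name="linear uptake chain">
    <listOfCompartments>
      <compartment id="c"/>
      <compartment id="e"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A_e" name="A external" compartment="e" boundaryCondition="false"/>
      <species id="A" name="A" compartment="c" boundaryCondition="false"/>
      <species id="B" name="B" compartment="c" boundaryCondition="false"/>
      <species id="X_bnd" name="sink" compartment="e" boundaryCondition="true"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="EX_A" reversible="true">
        <listOfReactants>
          <speciesReference species="A_e" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="X_bnd" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="-1"/>
            <parameter id="UPPER_BOUND" value="0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R_uptake" reversible="false">
        <listOfReactants>
          <speciesReference species="A_e" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R_convert" reversible="false">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="Biomass_drain" reversible="false">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1"/>
        </listOfReactants>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
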